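#' Construct a PPG signal object
#'
#' Container for a uniformly sampled single-channel photoplethysmogram.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units), length >= 2,
#'   all finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Start time in seconds.
#' @return An object of class `ppg_signal` with fields `samples`, `fs`, `t0`.
#' @export
ppg_signal <- function(samples, fs, t0 = 0) {
  if (!is.numeric(samples) || length(samples) < 2L)
    stop_arg("`samples` must be a numeric vector of length >= 2")
  if (any(!is.finite(samples)))
    stop_arg("`samples` must be finite (no NA/NaN/Inf)")
  check_scalar(fs, "fs", positive = TRUE)
  check_scalar(t0, "t0")
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "ppg_signal")
}

#' @export
print.ppg_signal <- function(x, ...) {
  cat(sprintf("PPG signal: %d samples @ %g Hz (%.2f s), amplitude [%.3g, %.3g]\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Time axis of a PPG signal
#' @param x A `ppg_signal`.
#' @return Numeric vector of sample times in seconds.
#' @export
signal_time <- function(x) {
  stopifnot(inherits(x, "ppg_signal"))
  x$t0 + (seq_along(x$samples) - 1L) / x$fs
}

#' @export
plot.ppg_signal <- function(x, ...) {
  graphics::plot(signal_time(x), x$samples, type = "l",
                 xlab = "time (s)", ylab = "amplitude (a.u.)", ...)
  invisible(x)
}

#' Beat morphology model
#'
#' Parameters of the per-heartbeat waveform used by the synthetic generator:
#' each beat is the sum of a systolic Gaussian and a delayed, smaller dicrotic
#' Gaussian.
#'
#' Width and delay defaults scale with the beat period (so fast and slow
#' hearts alike produce separable, physiologically proportioned beats): the
#' systolic Gaussian SD defaults to 15 percent of the period and the dicrotic
#' peak trails by 37.5 percent of the period. At the default 75 bpm these are
#' 0.12 s and 0.30 s.
#'
#' @param heart_rate Mean heart rate in beats/min, in (20, 250).
#' @param systolic_amp Systolic peak amplitude (a.u.).
#' @param systolic_width Systolic Gaussian SD in seconds.
#' @param dicrotic_amp Dicrotic peak amplitude (a.u.), must be < `systolic_amp`.
#' @param dicrotic_delay Delay of the dicrotic peak after the systolic peak (s).
#' @param dicrotic_width Dicrotic Gaussian SD in seconds.
#' @param hr_jitter_sd SD of per-beat period jitter in seconds (0 = metronomic).
#' @return An object of class `beat_model`.
#' @export
beat_model <- function(heart_rate = 75, systolic_amp = 1.0,
                       systolic_width = 0.15 * 60 / heart_rate,
                       dicrotic_amp = 0.35,
                       dicrotic_delay = 0.375 * 60 / heart_rate,
                       dicrotic_width = 1.5 * systolic_width,
                       hr_jitter_sd = 0.01) {
  check_scalar(heart_rate, "heart_rate", positive = TRUE)
  if (heart_rate <= 20 || heart_rate >= 250)
    stop_arg("`heart_rate` must be in (20, 250) bpm")
  check_scalar(systolic_amp, "systolic_amp", positive = TRUE)
  check_scalar(systolic_width, "systolic_width", positive = TRUE)
  check_scalar(dicrotic_amp, "dicrotic_amp", nonneg = TRUE)
  check_scalar(dicrotic_delay, "dicrotic_delay", positive = TRUE)
  check_scalar(dicrotic_width, "dicrotic_width", positive = TRUE)
  check_scalar(hr_jitter_sd, "hr_jitter_sd", nonneg = TRUE)
  if (dicrotic_amp >= systolic_amp)
    stop_arg("`dicrotic_amp` must be < `systolic_amp`")
  structure(list(heart_rate = heart_rate, systolic_amp = systolic_amp,
                 systolic_width = systolic_width, dicrotic_amp = dicrotic_amp,
                 dicrotic_delay = dicrotic_delay,
                 dicrotic_width = dicrotic_width,
                 hr_jitter_sd = hr_jitter_sd),
            class = "beat_model")
}

#' Additive noise model for synthetic PPG
#'
#' @param white_sd SD of additive white Gaussian noise (a.u.).
#' @param drift_amp Amplitude of sinusoidal baseline drift (a.u.).
#' @param drift_freq Baseline drift frequency in Hz.
#' @param artifact_rate Motion-artifact event rate, events per minute.
#' @param artifact_amp Amplitude of artifact transients (a.u.).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(white_sd = 0.05, drift_amp = 0.3, drift_freq = 0.05,
                        artifact_rate = 0, artifact_amp = 1.0) {
  for (nm in c("white_sd", "drift_amp", "drift_freq", "artifact_rate",
               "artifact_amp"))
    check_scalar(get(nm), nm, nonneg = TRUE)
  structure(list(white_sd = white_sd, drift_amp = drift_amp,
                 drift_freq = drift_freq, artifact_rate = artifact_rate,
                 artifact_amp = artifact_amp),
            class = "noise_model")
}

#' Glucose-to-morphology effect specification
#'
#' Defines how the blood glucose level (BGL) of a synthetic record perturbs the
#' beat morphology, so that downstream feature selection and regression have a
#' recoverable, known ground truth. Slopes are expressed in feature units per
#' mg/dL, relative to `ref_bgl`, and are translated internally into beat-model
#' adjustments:
#' \itemize{
#'   \item `pulse_width`: widens the systolic Gaussian so the half-amplitude
#'     pulse width changes by `slope` s per mg/dL (FWHM = 2.3548 sigma).
#'   \item `pulse_amplitude`: shifts the systolic amplitude by `slope` a.u.
#'     per mg/dL.
#'   \item `ipi`: shifts the inter-beat period by `slope` s per mg/dL.
#' }
#'
#' @param slopes Named numeric vector; names must be a subset of
#'   `c("pulse_width", "pulse_amplitude", "ipi")`.
#' @param ref_bgl Reference BGL (mg/dL) at which the nominal beat model holds.
#' @return An object of class `glucose_effect`.
#' @export
glucose_effect <- function(slopes = c(pulse_width = 4e-4,
                                      pulse_amplitude = 2e-3,
                                      ipi = -5e-4),
                           ref_bgl = 150) {
  allowed <- c("pulse_width", "pulse_amplitude", "ipi")
  if (length(slopes)) {
    if (is.null(names(slopes)) || !all(names(slopes) %in% allowed))
      stop_arg("`slopes` must be named with a subset of: ",
               paste(allowed, collapse = ", "))
    if (any(!is.finite(slopes))) stop_arg("`slopes` must be finite")
  }
  check_scalar(ref_bgl, "ref_bgl", positive = TRUE)
  structure(list(slopes = slopes, ref_bgl = ref_bgl,
                 affected_features = names(slopes),
                 informative_count = length(slopes)),
            class = "glucose_effect")
}

#' A glucose effect with all slopes zero
#' @return A `glucose_effect` that leaves the morphology untouched.
#' @export
no_glucose_effect <- function() glucose_effect(slopes = numeric(0))

# Apply the glucose effect to a beat model for a given BGL.
apply_glucose_effect <- function(beat, effect, bgl) {
  d <- bgl - effect$ref_bgl
  s <- effect$slopes
  b <- beat
  fwhm <- 2 * sqrt(2 * log(2))  # half-amplitude width of a Gaussian / sigma
  if ("pulse_width" %in% names(s))
    b$systolic_width <- max(0.02, b$systolic_width + s[["pulse_width"]] * d / fwhm)
  if ("pulse_amplitude" %in% names(s))
    b$systolic_amp <- max(0.2, b$systolic_amp + s[["pulse_amplitude"]] * d)
  if ("ipi" %in% names(s)) {
    period <- 60 / b$heart_rate + s[["ipi"]] * d
    period <- min(max(period, 60 / 245), 60 / 25)
    b$heart_rate <- 60 / period
  }
  if (b$dicrotic_amp >= b$systolic_amp) b$dicrotic_amp <- 0.9 * b$systolic_amp
  b
}

#' Classify a blood glucose level
#'
#' @param bgl Blood glucose in mg/dL (> 0); vectorized.
#' @param thresholds Length-2 numeric `(low, high)` with `0 < low < high`;
#'   defaults to the clinical 70/180 mg/dL band.
#' @return Factor with levels `hypo`, `normo`, `hyper`.
#' @export
label_class <- function(bgl, thresholds = c(70, 180)) {
  if (!is.numeric(bgl) || any(!is.finite(bgl)) || any(bgl <= 0))
    stop_arg("`bgl` must be positive and finite")
  if (length(thresholds) != 2L || thresholds[1] <= 0 ||
      thresholds[1] >= thresholds[2])
    stop_arg("`thresholds` must satisfy 0 < low < high")
  cls <- ifelse(bgl < thresholds[1], "hypo",
                ifelse(bgl > thresholds[2], "hyper", "normo"))
  factor(cls, levels = c("hypo", "normo", "hyper"))
}

#' Generate one synthetic PPG record
#'
#' Simulates a quasi-periodic PPG trace as a train of two-Gaussian beats
#' (systolic peak plus delayed dicrotic component) with additive white noise,
#' sinusoidal baseline drift and optional motion-artifact transients. The
#' record's BGL modulates beat morphology per the supplied
#' [glucose_effect()], and ground-truth systolic peak times are returned.
#'
#' Beats are laid down starting at half a period into the record, so with zero
#' jitter the beat count equals `floor(duration * heart_rate / 60 + 0.5)`.
#'
#' @param beat A [beat_model()].
#' @param noise A [noise_model()].
#' @param bgl Blood glucose in mg/dL (> 0).
#' @param duration Record length in seconds (> 2 beat periods).
#' @param fs Sampling rate in Hz (>= 50).
#' @param effect A [glucose_effect()]; default plants the standard effect.
#' @param seed Integer seed; identical seeds give byte-identical records.
#' @param thresholds Glucose class cut-offs passed to [label_class()].
#' @param subject_id Identifier stored in the record.
#' @return An object of class `ppg_record`: list with `signal` (a
#'   `ppg_signal`), `beat_times` (s), `bgl`, `glucose_class`, `subject_id`.
#' @export
generate_record <- function(beat = beat_model(), noise = noise_model(),
                            bgl = 100, duration = 10, fs = 100,
                            effect = glucose_effect(), seed = 1,
                            thresholds = c(70, 180), subject_id = "S1") {
  stopifnot(inherits(beat, "beat_model"), inherits(noise, "noise_model"),
            inherits(effect, "glucose_effect"))
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(fs, "fs", positive = TRUE)
  if (fs < 50) stop_arg("`fs` must be >= 50 Hz")
  if (!is.numeric(bgl) || length(bgl) != 1L || !is.finite(bgl) || bgl <= 0)
    stop_arg("`bgl` must be a positive scalar (mg/dL)")
  b <- apply_glucose_effect(beat, effect, bgl)
  period <- 60 / b$heart_rate
  if (duration <= 2 * period)
    stop_arg("`duration` must exceed two beat periods")

  with_seed(seed, {
    # Beat times: first beat at period/2, successive gaps jittered.
    beat_times <- numeric(0)
    t <- period / 2
    while (t < duration) {
      beat_times <- c(beat_times, t)
      gap <- period + if (b$hr_jitter_sd > 0) stats::rnorm(1, 0, b$hr_jitter_sd) else 0
      t <- t + max(gap, 0.25 * period)
    }
    n <- round(duration * fs)
    tt <- (seq_len(n) - 1L) / fs
    sig <- numeric(n)
    for (tb in beat_times) {
      sig <- sig + b$systolic_amp * exp(-((tt - tb)^2) / (2 * b$systolic_width^2)) +
        b$dicrotic_amp *
          exp(-((tt - tb - b$dicrotic_delay)^2) / (2 * b$dicrotic_width^2))
    }
    if (noise$drift_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      sig <- sig + noise$drift_amp * sin(2 * pi * noise$drift_freq * tt + phase)
    }
    if (noise$artifact_rate > 0) {
      n_art <- stats::rpois(1, noise$artifact_rate * duration / 60)
      if (n_art > 0) {
        centers <- stats::runif(n_art, 0, duration)
        signs <- sample(c(-1, 1), n_art, replace = TRUE)
        for (k in seq_len(n_art))
          sig <- sig + signs[k] * noise$artifact_amp *
            exp(-((tt - centers[k])^2) / (2 * 0.15^2))
      }
    }
    if (noise$white_sd > 0) sig <- sig + stats::rnorm(n, 0, noise$white_sd)

    structure(list(signal = ppg_signal(sig, fs, 0),
                   beat_times = beat_times,
                   bgl = bgl,
                   glucose_class = label_class(bgl, thresholds),
                   subject_id = subject_id),
              class = "ppg_record")
  })
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("Synthetic PPG record %s: %d beats, BGL %.1f mg/dL (%s)\n",
              x$subject_id, length(x$beat_times), x$bgl,
              as.character(x$glucose_class)))
  print(x$signal)
  invisible(x)
}

#' Generate per-client federated datasets of synthetic PPG records
#'
#' Emulates `K` healthcare sites, each holding its own synthetic PPG records
#' with reference BGLs. The `heterogeneity` parameter shifts each client's BGL
#' distribution mean by up to +/- `heterogeneity * 25` mg/dL and scales its
#' white-noise level, emulating cross-site diversity. With `K = 1` the result
#' is the pooled generation at the same seed.
#'
#' @param n_clients Number of clients `K` (>= 1).
#' @param records_per_client Integer vector of per-client record counts
#'   (recycled to length `K`); all positive.
#' @param effect A [glucose_effect()].
#' @param heterogeneity Non-negative scalar; 0 = identically distributed sites.
#' @param seed Integer seed for the whole collection.
#' @param beat,noise Nominal [beat_model()] / [noise_model()].
#' @param duration,fs Per-record signal length (s) and sampling rate (Hz).
#' @param bgl_range Length-2 range of the uniform BGL draw, mg/dL.
#' @param thresholds Glucose class cut-offs.
#' @return List of `K` objects of class `client_records`, each a list with
#'   `client_id`, `records` (list of `ppg_record`), `bgl`, `class`.
#' @export
generate_federated_datasets <- function(n_clients = 5,
                                        records_per_client = 100,
                                        effect = glucose_effect(),
                                        heterogeneity = 0.5,
                                        seed = 1,
                                        beat = beat_model(),
                                        noise = noise_model(),
                                        duration = 10, fs = 100,
                                        bgl_range = c(50, 300),
                                        thresholds = c(70, 180)) {
  check_scalar(n_clients, "n_clients", positive = TRUE)
  if (length(records_per_client) == 0L || any(records_per_client <= 0))
    stop_arg("`records_per_client` must be positive")
  check_scalar(heterogeneity, "heterogeneity", nonneg = TRUE)
  sizes <- rep_len(as.integer(records_per_client), n_clients)

  offsets <- with_seed(derive_seed(seed, 0L), {
    list(bgl = stats::runif(n_clients, -1, 1) * 25 * heterogeneity,
         noise = 1 + heterogeneity * stats::runif(n_clients, 0, 0.5))
  })

  lapply(seq_len(n_clients), function(i) {
    ni <- sizes[i]
    cl_noise <- noise
    cl_noise$white_sd <- noise$white_sd * offsets$noise[i]
    bgls <- with_seed(derive_seed(seed, i), {
      pmin(pmax(stats::runif(ni, bgl_range[1], bgl_range[2]) + offsets$bgl[i],
                40), 420)
    })
    recs <- lapply(seq_len(ni), function(j) {
      generate_record(beat = beat, noise = cl_noise, bgl = bgls[j],
                      duration = duration, fs = fs, effect = effect,
                      seed = derive_seed(seed, i * 100000L + j),
                      thresholds = thresholds,
                      subject_id = sprintf("C%02d-R%04d", i, j))
    })
    structure(list(client_id = sprintf("C%02d", i), records = recs,
                   bgl = bgls,
                   class = label_class(bgls, thresholds)),
              class = "client_records")
  })
}

#' @export
print.client_records <- function(x, ...) {
  cat(sprintf("Client %s: %d records, BGL mean %.1f mg/dL\n",
              x$client_id, length(x$records), mean(x$bgl)))
  invisible(x)
}

#' Simulate a feature matrix with planted informative features
#'
#' Generates a labelled feature matrix directly (bypassing signal synthesis)
#' with `n_informative` features that are *complementary* noisy linear views
#' of the standardized BGL, and the remainder pure standard-normal noise.
#' The per-feature noise components are constructed to sum to zero across the
#' informative set, so the full informative ensemble recovers the BGL signal
#' exactly while every proper subset retains residual noise: the planted set
#' is the unique jointly sufficient subset, giving feature selection a
#' well-defined ground truth to recover.
#'
#' @param n Number of rows.
#' @param d Total number of features.
#' @param n_informative Number of informative features (<= d); they occupy the
#'   first `n_informative` columns with alternating signs.
#' @param noise_sd Scale of the per-feature noise components (the signal
#'   component has unit SD).
#' @param bgl_range Uniform BGL range, mg/dL.
#' @param thresholds Glucose class cut-offs.
#' @param seed Integer seed.
#' @return A `feature_matrix` (see [feature_matrix()]) with attribute
#'   `informative` giving the indices of the planted features.
#' @export
simulate_feature_matrix <- function(n = 300, d = 10, n_informative = 3,
                                    noise_sd = 0.7, bgl_range = c(50, 300),
                                    thresholds = c(70, 180), seed = 1) {
  stopifnot(n_informative <= d, n >= 2)
  with_seed(seed, {
    bgl <- stats::runif(n, bgl_range[1], bgl_range[2])
    z <- (bgl - mean(bgl_range)) / (diff(bgl_range) / sqrt(12))
    x <- matrix(stats::rnorm(n * d), n, d)
    if (n_informative > 0L) {
      eta <- matrix(stats::rnorm(n * n_informative, 0, noise_sd),
                    n, n_informative)
      eta <- eta - rowMeans(eta)  # zero-sum across the informative set
      for (j in seq_len(n_informative)) {
        s <- if (j %% 2L == 1L) 1 else -1
        x[, j] <- s * (z + eta[, j])
      }
    }
    colnames(x) <- sprintf("F%02d", seq_len(d))
    fm <- feature_matrix(x, bgl = bgl, class = label_class(bgl, thresholds))
    attr(fm, "informative") <- seq_len(n_informative)
    fm
  })
}
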