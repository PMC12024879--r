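#' Canonical feature names, in frozen order
#'
#' The 13 per-record PPG features: six time-domain, three frequency-domain,
#' four nonlinear. The order is frozen so that feature-mask bit indices remain
#' stable across the package.
#'
#' @return Character vector of length 13.
#' @export
ppg_feature_names <- function() {
  c("pulse_width", "pulse_amplitude", "ipi", "auc",
    "slope_upstroke", "slope_downstroke",
    "hrv_sdnn", "psd_db", "dominant_freq",
    "fractal_dim", "entropy", "sd1", "sd2")
}

#' Labelled feature matrix container
#'
#' @param x Numeric matrix, rows = records/cycles, named columns.
#' @param bgl Optional reference BGL per row (mg/dL).
#' @param class Optional glucose class per row.
#' @return Object of class `feature_matrix`: list with `x`, `bgl`, `class`.
#' @export
feature_matrix <- function(x, bgl = NULL, class = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop_arg("feature matrix needs at least one row")
  if (is.null(colnames(x))) stop_arg("feature matrix needs column names")
  if (!is.null(bgl) && length(bgl) != nrow(x))
    stop_arg("`bgl` length must match rows")
  if (!is.null(class) && length(class) != nrow(x))
    stop_arg("`class` length must match rows")
  structure(list(x = x, bgl = bgl, class = class), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d records x %d features%s\n",
              nrow(x$x), ncol(x$x),
              if (!is.null(x$bgl)) " (labelled)" else ""))
  invisible(x)
}

#' Drop rows with missing feature values
#'
#' @param fm A [feature_matrix()].
#' @param quiet Suppress the dropped-row message.
#' @return The filtered `feature_matrix`; errors if nothing survives.
#' @export
drop_incomplete <- function(fm, quiet = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  ok <- stats::complete.cases(fm$x)
  if (!all(ok) && !quiet)
    message(sum(!ok), " record(s) dropped for missing feature values")
  if (!any(ok)) stop_arg("no complete records left after filtering")
  feature_matrix(fm$x[ok, , drop = FALSE], fm$bgl[ok], fm$class[ok])
}

# Welch power spectral density (hann window, 50% overlap), one-sided,
# density units (power per Hz).
welch_psd <- function(x, fs, nperseg = min(512L, length(x))) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nperseg) / (nperseg + 1)))
  U <- sum(w^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nf)]
    acc <- acc + Mod(X)^2
  }
  p <- acc / (length(starts) * U * fs)
  # fold the two-sided spectrum (all bins except DC and Nyquist appear twice)
  if (nperseg %% 2L == 0L) p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
  else p[2:nf] <- 2 * p[2:nf]
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = p)
}

# Higuchi fractal dimension with k_max curve lengths.
higuchi_fd <- function(x, k_max = 8L) {
  n <- length(x)
  if (n < 64L) return(NA_real_)
  ks <- seq_len(k_max)
  Lk <- vapply(ks, function(k) {
    Lm <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2L) return(NA_real_)
      norm <- (n - 1) / ((length(idx) - 1L) * k)
      sum(abs(diff(x[idx]))) * norm / k
    }, numeric(1))
    mean(Lm, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(log(Lk))
  if (sum(ok) < 2L) return(NA_real_)
  unname(stats::coef(stats::lm(log(Lk[ok]) ~ log(1 / ks[ok])))[2L])
}

#' Time-domain features
#'
#' Per-record means over cycles of: half-amplitude pulse width (s), raw-segment
#' amplitude max - min (a.u.), mean inter-pulse interval (s), trapezoidal area
#' of the normalized cycle over its time span, and the steepest upstroke /
#' downstroke slopes of the raw segment (forward difference times `fs`,
#' a.u./s). Amplitude is computed on the raw segment because the normalized
#' trace has unit amplitude by construction.
#'
#' @param cycles List of `normalized_cycle` from [extract_cycles()].
#' @param peaks A `peak_list`.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector of the six time-domain features; `ipi` is `NA`
#'   with fewer than two peaks.
#' @export
time_domain_features <- function(cycles, peaks, fs) {
  if (!length(cycles))
    return(stats::setNames(rep(NA_real_, 6), ppg_feature_names()[1:6]))
  per <- vapply(cycles, function(cy) {
    v <- cy$values
    span <- diff(cy$source_span)
    above <- which(v >= 0.5)
    width <- if (length(above) >= 2L)
      (above[length(above)] - above[1L]) / (cy$Lg - 1L) * span else NA_real_
    amp <- diff(range(cy$raw))
    tt <- seq(0, span, length.out = cy$Lg)
    auc <- trapz(tt, v)
    dv <- diff(cy$raw) * fs
    c(width = width, amp = amp, auc = auc,
      up = if (length(dv)) max(dv) else NA_real_,
      down = if (length(dv)) abs(min(dv)) else NA_real_)
  }, numeric(5))
  ipi <- if (length(peaks$indices) >= 2L)
    mean(diff(peaks$indices)) / fs else NA_real_
  stats::setNames(c(mean(per["width", ], na.rm = TRUE),
                    mean(per["amp", ]), ipi, mean(per["auc", ]),
                    mean(per["up", ]), mean(per["down", ])),
                  ppg_feature_names()[1:6])
}

#' Frequency-domain features
#'
#' HRV as the SDNN of the inter-pulse-interval series (ms); a spectral power
#' summary, `10 log10` of the total Welch power in the 0.5-8 Hz band (dB); and
#' the dominant frequency, the Welch-PSD argmax within 0.5-3 Hz. Signals
#' shorter than 10 s yield missing spectral values.
#'
#' @param signal A [ppg_signal()].
#' @param peaks A `peak_list` for the HRV term.
#' @return Named numeric vector of the three frequency-domain features.
#' @export
frequency_domain_features <- function(signal, peaks) {
  nms <- ppg_feature_names()[7:9]
  hrv <- if (length(peaks$indices) >= 3L)
    stats::sd(diff(peaks$indices) / peaks$fs * 1000) else NA_real_
  n <- length(signal$samples)
  if (n / signal$fs < 10) {
    return(stats::setNames(c(hrv, NA_real_, NA_real_), nms))
  }
  w <- welch_psd(signal$samples, signal$fs)
  df <- w$freq[2L] - w$freq[1L]
  band <- w$freq >= 0.5 & w$freq <= 8
  total <- sum(w$psd[band]) * df
  psd_db <- if (total > 0) 10 * log10(total) else NA_real_
  dom <- w$freq >= 0.5 & w$freq <= 3
  domf <- if (any(dom)) w$freq[dom][which.max(w$psd[dom])] else NA_real_
  stats::setNames(c(hrv, psd_db, domf), nms)
}

#' Nonlinear features
#'
#' Higuchi fractal dimension (`k_max = 8`); Shannon entropy (bits) of a 16-bin
#' amplitude histogram of the min-max-normalized signal; and the Poincare
#' descriptors of the inter-pulse intervals in ms,
#' `SD1 = sqrt(var(diff(IPI)) / 2)` and
#' `SD2 = sqrt(2 var(IPI) - var(diff(IPI)) / 2)`.
#'
#' @param signal A [ppg_signal()] (>= 64 samples for FD/entropy).
#' @param peaks A `peak_list` (>= 4 peaks, i.e. >= 3 intervals, for Poincare).
#' @return Named numeric vector of the four nonlinear features.
#' @export
nonlinear_features <- function(signal, peaks) {
  nms <- ppg_feature_names()[10:13]
  x <- signal$samples
  fd <- higuchi_fd(x, 8L)
  ent <- if (length(x) >= 64L) {
    rng <- range(x)
    if (rng[2] > rng[1]) {
      z <- (x - rng[1]) / (rng[2] - rng[1])
      h <- tabulate(pmin(floor(z * 16) + 1L, 16L), 16L)
      p <- h / sum(h)
      p <- p[p > 0]
      -sum(p * log2(p))
    } else 0
  } else NA_real_
  ipi_ms <- diff(peaks$indices) / peaks$fs * 1000
  if (length(ipi_ms) >= 3L) {
    vd <- stats::var(diff(ipi_ms))
    vi <- stats::var(ipi_ms)
    sd1 <- sqrt(vd / 2)
    sd2 <- sqrt(max(2 * vi - vd / 2, 0))
  } else {
    sd1 <- sd2 <- NA_real_
  }
  stats::setNames(c(fd, ent, sd1, sd2), nms)
}

#' Extract the 13-feature vector of one record
#'
#' Segments the signal with [segment_ppg()] (optionally after [denoise()])
#' and concatenates the time-domain, frequency-domain and nonlinear feature
#' groups in the frozen [ppg_feature_names()] order.
#'
#' @param x A `ppg_record` or [ppg_signal()].
#' @param Lg Normalized cycle length.
#' @param min_hr,max_hr Heart-rate band for peak detection (bpm).
#' @param preprocess `"none"` or `"denoise"`; whether to CWT-denoise first.
#' @param ... Passed to [denoise()] when `preprocess = "denoise"`.
#' @return Named numeric vector of length 13 (entries may be `NA` when the
#'   record is too short or too few beats are found).
#' @export
extract_features <- function(x, Lg = 100, min_hr = 40, max_hr = 180,
                             preprocess = c("none", "denoise"), ...) {
  preprocess <- match.arg(preprocess)
  signal <- if (inherits(x, "ppg_record")) x$signal else x
  stopifnot(inherits(signal, "ppg_signal"))
  if (preprocess == "denoise") signal <- denoise(signal, ...)
  seg <- segment_ppg(signal, Lg = Lg, min_hr = min_hr, max_hr = max_hr)
  c(time_domain_features(seg$cycles, seg$peaks, signal$fs),
    frequency_domain_features(signal, seg$peaks),
    nonlinear_features(signal, seg$peaks))
}

#' Build a labelled feature matrix from a list of records
#'
#' @param records List of `ppg_record`.
#' @param drop_missing Drop rows with any missing feature (logged).
#' @inheritParams extract_features
#' @return A [feature_matrix()] with `bgl` and `class` labels.
#' @export
build_feature_matrix <- function(records, Lg = 100, min_hr = 40,
                                 max_hr = 180,
                                 preprocess = c("none", "denoise"),
                                 drop_missing = TRUE, ...) {
  stopifnot(length(records) >= 1L)
  rows <- t(vapply(records, extract_features, numeric(13), Lg = Lg,
                   min_hr = min_hr, max_hr = max_hr,
                   preprocess = preprocess, ...))
  fm <- feature_matrix(rows,
                       bgl = vapply(records, function(r) r$bgl, numeric(1)),
                       class = factor(vapply(records, function(r)
                         as.character(r$glucose_class), character(1)),
                         levels = c("hypo", "normo", "hyper")))
  if (drop_missing) drop_incomplete(fm) else fm
}

#' Per-client feature datasets for federated training
#'
#' Runs feature extraction over every record of every client, keeping the
#' client partition intact (only the resulting feature rows and labels — never
#' raw signals — are what federated training consumes).
#'
#' @param clients List of `client_records` from
#'   [generate_federated_datasets()].
#' @inheritParams build_feature_matrix
#' @return List of [feature_matrix()] objects, one per client, each with a
#'   `client_id` attribute.
#' @export
client_feature_matrices <- function(clients, Lg = 100, min_hr = 40,
                                    max_hr = 180,
                                    preprocess = c("none", "denoise"), ...) {
  lapply(clients, function(cl) {
    fm <- build_feature_matrix(cl$records, Lg = Lg, min_hr = min_hr,
                               max_hr = max_hr, preprocess = preprocess, ...)
    attr(fm, "client_id") <- cl$client_id
    fm
  })
}
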