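make_peaks <- function(indices, fs = 100) {
  structure(list(indices = as.integer(indices), fs = fs),
            class = "peak_list")
}

make_cycle <- function(raw, span_s, Lg = 100) {
  v <- stats::approx(seq_along(raw), raw, n = Lg)$y
  v <- (v - min(v)) / (max(v) - min(v))
  structure(list(values = v, raw = raw, source_span = c(0, span_s), Lg = Lg),
            class = "normalized_cycle")
}

test_that("time-domain features match closed forms", {
  # amplitude is computed on the RAW segment (normalized trace is always 0-1)
  cy <- make_cycle(c(2, 3, 4, 6, 4, 3, 2), span_s = 0.06, Lg = 8)
  td <- time_domain_features(list(cy), make_peaks(integer(0)), fs = 100)
  expect_equal(unname(td["pulse_amplitude"]), 4)
  expect_true(is.na(td["ipi"]))  # < 2 peaks

  # peaks at 1, 2, 3 s -> mean IPI exactly 1 s
  td2 <- time_domain_features(list(cy), make_peaks(c(101, 201, 301)), 100)
  expect_equal(unname(td2["ipi"]), 1.0)

  # triangle rising 0 -> 1 over 0.25 s at fs = 100: upstroke slope 4 a.u./s
  tri <- c(seq(0, 1, length.out = 26), seq(1, 0, length.out = 51)[-1])
  cyt <- make_cycle(tri, span_s = length(tri) / 100)
  td3 <- time_domain_features(list(cyt), make_peaks(integer(0)), 100)
  expect_equal(unname(td3["slope_upstroke"]), 4, tolerance = 0.05)
  expect_equal(unname(td3["slope_downstroke"]), 2, tolerance = 0.05)
})

test_that("pulse width measures the half-amplitude crossing span", {
  # rectangular-ish pulse occupying the middle half of a 1 s cycle
  raw <- c(rep(0, 25), rep(1, 50), rep(0, 25))
  cy <- make_cycle(raw, span_s = 1, Lg = 100)
  td <- time_domain_features(list(cy), make_peaks(integer(0)), 100)
  expect_equal(unname(td["pulse_width"]), 0.5, tolerance = 0.03)
})

test_that("frequency-domain features match spectral oracles", {
  fs <- 100
  tt <- seq(0, 20, by = 1 / fs)[-1]
  s <- ppg_signal(sin(2 * pi * 1.2 * tt), fs)
  # constant IPI -> HRV (SDNN) exactly 0; irregular IPI -> positive
  fd <- frequency_domain_features(s, make_peaks(cumsum(c(50, 80, 95, 70, 88)),
                                                fs))
  expect_gt(fd["hrv_sdnn"], 0)
  fd0 <- frequency_domain_features(s, make_peaks(seq(100, 1900, by = 100), fs))
  expect_equal(unname(fd0["hrv_sdnn"]), 0)

  # dominant frequency of a pure 1.2 Hz tone, within the Welch resolution;
  # cross-checked against a densely padded FFT oracle
  expect_lt(abs(fd0["dominant_freq"] - 1.2), fs / 512)
  pad <- c(s$samples, rep(0, 2^15 - length(s$samples)))
  spec_oracle <- Mod(stats::fft(pad))[1:2^14]
  f_oracle <- (which.max(spec_oracle) - 1) * fs / 2^15
  expect_lt(abs(fd0["dominant_freq"] - f_oracle), fs / 512)

  # doubling the amplitude raises band power by 20 log10(2) dB
  s2 <- ppg_signal(2 * s$samples, fs)
  fd2 <- frequency_domain_features(s2, make_peaks(seq(100, 1900, 100), fs))
  expect_equal(unname(fd2["psd_db"] - fd0["psd_db"]), 20 * log10(2),
               tolerance = 1e-8)

  # too-short signal -> missing spectral markers
  short <- ppg_signal(sin(2 * pi * tt[1:300]), fs)
  fds <- frequency_domain_features(short, make_peaks(c(10, 110, 210), fs))
  expect_true(is.na(fds["psd_db"]) && is.na(fds["dominant_freq"]))
})

test_that("nonlinear features match closed forms and the rotation oracle", {
  const <- ppg_signal(rep(3, 128), 100)
  nl <- nonlinear_features(const, make_peaks(integer(0)))
  expect_equal(unname(nl["entropy"]), 0)

  # constant IPI -> SD1 = SD2 = 0
  nl0 <- nonlinear_features(ppg_signal(rnorm(128), 100),
                            make_peaks(c(100, 200, 300, 400, 500), 100))
  expect_equal(unname(nl0["sd1"]), 0)
  expect_equal(unname(nl0["sd2"]), 0)

  # variance formulas vs independent rotated-scatter oracle. SD1's identity
  # var(diff)/2 is exact for any series; SD2's variance form (2 var(IPI) -
  # var(diff)/2) equals the rotated major-axis SD only asymptotically, so it
  # is checked on a long stationary series.
  ipi_ms <- c(800, 820, 790, 810)
  idx <- cumsum(c(100, ipi_ms))  # fs = 1000 -> samples are milliseconds
  nl1 <- nonlinear_features(ppg_signal(rnorm(3000), 1000),
                            make_peaks(idx, 1000))
  orc <- oracle_poincare(ipi_ms)
  expect_equal(unname(nl1["sd1"]), unname(orc["sd1"]), tolerance = 1e-10)
  set.seed(31)
  long_ipi <- round(800 + 25 * rnorm(200))
  idx2 <- cumsum(c(100, long_ipi))
  nl2 <- nonlinear_features(ppg_signal(rnorm(max(idx2) + 10), 1000),
                            make_peaks(idx2, 1000))
  orc2 <- oracle_poincare(long_ipi)
  expect_equal(unname(nl2["sd1"]), unname(orc2["sd1"]), tolerance = 0.02)
  expect_equal(unname(nl2["sd2"]), unname(orc2["sd2"]), tolerance = 0.05)

  # Higuchi FD ordering: straight line below white noise
  line <- nonlinear_features(ppg_signal(seq(0, 1, length.out = 256), 100),
                             make_peaks(integer(0)))
  set.seed(4)
  noise <- nonlinear_features(ppg_signal(rnorm(256), 100),
                              make_peaks(integer(0)))
  expect_lt(line["fractal_dim"], noise["fractal_dim"])
  expect_equal(unname(line["fractal_dim"]), 1, tolerance = 0.1)
})

test_that("the feature vector is 13-long, ordered, and deterministic", {
  r <- clean_record(duration = 12)
  f <- extract_features(r)
  expect_length(f, 13L)
  expect_identical(names(f), ppg_feature_names())
  expect_true(all(is.finite(f)))
  expect_identical(f, extract_features(r))

  # a start-time shift relabels the axis only; features are unchanged
  shifted <- r
  shifted$signal$t0 <- 5
  expect_equal(extract_features(shifted), f)
})

test_that("planted glucose effects surface as signed feature correlations", {
  n <- 50
  bgls <- seq(55, 295, length.out = n)
  eff <- glucose_effect()  # width +, amplitude +, ipi -
  F <- t(vapply(seq_len(n), function(i) {
    extract_features(generate_record(
      noise = noise_model(white_sd = 0, drift_amp = 0), bgl = bgls[i],
      effect = eff, seed = 300 + i))
  }, numeric(13)))
  expect_gt(stats::cor(bgls, F[, "pulse_width"]), 0.5)
  expect_gt(stats::cor(bgls, F[, "pulse_amplitude"]), 0.5)
  expect_lt(stats::cor(bgls, F[, "ipi"]), -0.5)

  # with only the amplitude slope active, rhythm features stay uncorrelated
  eff_amp <- glucose_effect(slopes = c(pulse_amplitude = 2e-3))
  F2 <- t(vapply(seq_len(n), function(i) {
    extract_features(generate_record(
      noise = noise_model(white_sd = 0, drift_amp = 0), bgl = bgls[i],
      effect = eff_amp, seed = 600 + i))
  }, numeric(13)))
  expect_gt(stats::cor(bgls, F2[, "pulse_amplitude"]), 0.9)
  uncorrelated <- function(v) {
    if (stats::sd(v) == 0) return(TRUE)  # constant: trivially unassociated
    abs(stats::cor(bgls, v)) < 0.3
  }
  expect_true(uncorrelated(F2[, "ipi"]))
  expect_true(uncorrelated(F2[, "dominant_freq"]))
})

test_that("feature matrices carry labels and drop incomplete rows", {
  recs <- lapply(1:4, function(i)
    generate_record(bgl = 60 + 50 * i, seed = i, duration = 12))
  fm <- build_feature_matrix(recs)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(nrow(fm$x), 4L)
  expect_equal(fm$bgl, c(110, 160, 210, 260))
  expect_equal(as.character(fm$class), c("normo", "normo", "hyper", "hyper"))

  fm$x[2, 3] <- NA
  expect_message(kept <- drop_incomplete(fm), "dropped")
  expect_equal(nrow(kept$x), 3L)
})
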