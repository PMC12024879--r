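# Helper: wrap a plain matrix as wavelet coefficients.
coeffs_of <- function(m, scales = seq_len(nrow(m)), fs = 100,
                      spec = wavelet_spec()) {
  structure(list(matrix = m, grid = scale_grid(scales), spec = spec, fs = fs),
            class = "wavelet_coefficients")
}

test_that("cwt matches direct numerical integration of the defining integral", {
  fs <- 50
  tt <- seq(0, 4, by = 1 / fs)[-1]
  x <- sin(2 * pi * 1.3 * tt) + 0.4 * cos(2 * pi * 2.7 * tt)
  s <- ppg_signal(x, fs)
  for (fam in c("mexican_hat", "morlet")) {
    spec <- wavelet_spec(fam)
    scales <- freq_to_scale(c(3, 2, 1), spec)
    W <- cwt_ppg(s, scale_grid(scales), spec)
    O <- oracle_cwt(x, fs, scales, spec)
    if (fam == "mexican_hat") O <- Re(O)
    expect_lt(max(Mod(W$matrix - O)), 1e-6 * max(Mod(O)))
  }
})

test_that("cwt is linear and maps a sinusoid to its pseudo-frequency", {
  fs <- 100
  s <- ppg_signal(sin(2 * pi * 1 * seq(0, 20, by = 1 / fs)[-1]), fs)
  spec <- wavelet_spec("mexican_hat")
  grid <- default_scale_grid(0.5, 4, 25, spec)

  z <- ppg_signal(rep(0, 500), fs)
  expect_true(all(cwt_ppg(z, grid, spec)$matrix == 0))

  W1 <- cwt_ppg(s, grid, spec)
  s3 <- ppg_signal(3 * s$samples, fs)
  expect_equal(cwt_ppg(s3, grid, spec)$matrix, 3 * W1$matrix,
               tolerance = 1e-12)

  # the scale with maximal mean |coefficient| maps to ~1 Hz
  pf <- scale_to_freq(grid$scales, spec)
  jmax <- which.max(rowMeans(abs(W1$matrix)))
  step <- exp(abs(diff(log(pf[1:2]))))
  expect_lt(abs(log(pf[jmax] / 1)), log(step) * 1.5)

  expect_error(cwt_ppg(structure(list(samples = c(1, NaN), fs = 10, t0 = 0),
                                 class = "ppg_signal"), grid, spec),
               "non-finite")
  expect_warning(cwt_ppg(ppg_signal(rnorm(50), 100), scale_grid(c(0.1, 2)),
                         spec),
                 "exceed")
})

test_that("universal threshold equals sigma * sqrt(2 ln N)", {
  expect_equal(universal_threshold(5, 1)$T, 0)
  expect_equal(universal_threshold(2, 1024)$T, 2 * sqrt(2 * log(1024)),
               tolerance = 1e-15)
  ts <- vapply(c(2, 8, 64, 4096), function(n) universal_threshold(1.5, n)$T,
               numeric(1))
  expect_true(all(diff(ts) >= 0))
  expect_error(universal_threshold(-1, 10), "sigma")
})

test_that("noise sigma estimator is robust, homogeneous and near-unbiased", {
  expect_equal(estimate_noise_sigma(coeffs_of(matrix(0, 3, 40))), 0)

  spec <- wavelet_spec("mexican_hat")
  grid <- scale_grid(freq_to_scale(c(8, 4, 2), spec))
  sigma_w <- 0.7
  est <- mc <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    sig <- ppg_signal(rnorm(4096, 0, sigma_w), 100)
    W <- cwt_ppg(sig, grid, spec)
    est[s] <- estimate_noise_sigma(W)
    mc[s] <- stats::sd(W$matrix[1, ])  # Monte-Carlo oracle: empirical SD
  }
  expect_lt(abs(mean(est) - mean(mc)) / mean(mc), 0.15)

  # homogeneity: scaling the input scales the estimate
  set.seed(1)
  sig <- ppg_signal(rnorm(1024), 100)
  W <- cwt_ppg(sig, grid, spec)
  W3 <- W
  W3$matrix <- 3 * W$matrix
  expect_equal(estimate_noise_sigma(W3), 3 * estimate_noise_sigma(W),
               tolerance = 1e-12)
})

test_that("soft thresholding shrinks exactly per the branch rules", {
  W <- coeffs_of(matrix(c(1.5, 5, -5, 0), 1))
  out <- soft_threshold(W, universal_threshold(2 / sqrt(2 * log(4)), 4))
  expect_equal(as.numeric(out$matrix), c(0, 3, -3, 0))

  # contraction + energy non-increase + idempotence at T = 0
  set.seed(3)
  W <- coeffs_of(matrix(rnorm(200), 4))
  out <- soft_threshold(W, list(T = 0.8))
  expect_true(all(abs(out$matrix) <= abs(W$matrix)))
  expect_lte(sum(out$matrix^2), sum(W$matrix^2))
  expect_equal(soft_threshold(W, list(T = 0))$matrix, W$matrix)

  # complex (Morlet) coefficients: modulus shrunk, phase preserved
  Wc <- coeffs_of(matrix(complex(modulus = c(5, 1), argument = c(1, 2)), 1),
                  spec = wavelet_spec("morlet"))
  outc <- soft_threshold(Wc, list(T = 2))
  expect_equal(Mod(outc$matrix), matrix(c(3, 0), 1))
  expect_equal(Arg(outc$matrix[1, 1]), 1, tolerance = 1e-12)
})

test_that("icwt inverts cwt within 5 percent on band-limited signals", {
  fs <- 100
  tt <- seq(0, 30, by = 1 / fs)[-1]
  edge <- pmin(tt, 30 - tt)
  win <- ifelse(edge > 3, 1, 0.5 * (1 - cos(pi * edge / 3)))
  x <- (sin(2 * pi * 1.1 * tt) + 0.5 * sin(2 * pi * 2.3 * tt)) * win
  for (fam in c("mexican_hat", "morlet")) {
    spec <- wavelet_spec(fam)
    grid <- default_scale_grid(0.4, 10, 64, spec)
    rec <- icwt_ppg(cwt_ppg(ppg_signal(x, fs), grid, spec))
    expect_lt(sqrt(sum((rec$samples - x)^2) / sum(x^2)), 0.05)
    expect_length(rec$samples, length(x))
    expect_equal(rec$fs, fs)
  }
})

test_that("icwt is linear and maps zero to zero", {
  spec <- wavelet_spec("mexican_hat")
  grid <- default_scale_grid(0.5, 4, 10, spec)
  set.seed(2)
  s <- ppg_signal(rnorm(300), 100)
  W <- cwt_ppg(s, grid, spec)
  Wz <- W
  Wz$matrix[] <- 0
  expect_true(all(icwt_ppg(Wz)$samples == 0))
  W2 <- W
  W2$matrix <- 2 * W$matrix
  sum12 <- W
  sum12$matrix <- W$matrix + W2$matrix
  expect_equal(icwt_ppg(sum12)$samples,
               icwt_ppg(W)$samples + icwt_ppg(W2)$samples, tolerance = 1e-10)
})

test_that("denoising reconstructs clean signals and suppresses drift", {
  clean <- clean_record(duration = 20, seed = 5)
  out <- denoise(clean$signal)
  expect_gt(stats::cor(out$samples, clean$signal$samples), 0.99)
  expect_length(out$samples, length(clean$signal$samples))
  expect_equal(out$fs, clean$signal$fs)

  # pure 0.05 Hz drift of amplitude 5: >= 80% amplitude reduction
  tt <- signal_time(clean$signal)
  drifty <- ppg_signal(clean$signal$samples + 5 * sin(2 * pi * 0.05 * tt + 0.7),
                       clean$signal$fs)
  dn <- denoise(drifty)
  amp_of <- function(y) {
    f <- stats::lm(y ~ sin(2 * pi * 0.05 * tt) + cos(2 * pi * 0.05 * tt))
    sqrt(sum(stats::coef(f)[2:3]^2))
  }
  expect_gt(amp_of(drifty$samples), 4.5)
  expect_lt(amp_of(dn$samples), 0.2 * amp_of(drifty$samples))
})

test_that("denoising reduces RMSE to the clean oracle on noisy records", {
  wins <- 0L
  for (s in 1:10) {
    cl <- clean_record(seed = s, duration = 10)
    ny <- generate_record(noise = noise_model(white_sd = 0.15,
                                              drift_amp = 0.3),
                          bgl = 120, duration = 10,
                          effect = no_glucose_effect(), seed = s)
    dn <- denoise(ny$signal)
    wins <- wins +
      (rmse_to(dn$samples, cl$signal$samples) <
         rmse_to(ny$signal$samples, cl$signal$samples))
  }
  expect_gte(wins, 9L)
})
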