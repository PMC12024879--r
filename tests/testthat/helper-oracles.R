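# Independent oracles, deliberately coded along different routes than the
# package implementation.

# Direct time-domain CWT by numerical integration of the defining integral
# (O(n * m) loop; no FFT). Used to check the convolution-based path.
oracle_cwt <- function(samples, fs, scales, spec) {
  n <- length(samples)
  tt <- (seq_len(n) - 1) / fs
  out <- matrix(0i, length(scales), n)
  for (j in seq_along(scales)) {
    a <- scales[j]
    for (yi in seq_len(n)) {
      arg <- (tt - tt[yi]) / a
      psi <- switch(spec$family,
        mexican_hat = (2 / (sqrt(3) * pi^0.25)) * (1 - arg^2) * exp(-arg^2 / 2),
        morlet = pi^(-0.25) * exp(-arg^2 / 2) *
          exp(1i * 2 * pi * spec$f0 * arg))
      out[j, yi] <- sum(samples * Conj(psi)) / fs / sqrt(a)
    }
  }
  out
}

# Scalar Clarke error-grid lookup, written as a literal decision ladder over
# the 1987 zone geometry (independent of the vectorized implementation).
oracle_clarke_zone <- function(ref, pred) {
  # clinically accurate: within 20% or joint hypoglycaemic agreement
  if (abs(pred - ref) <= 0.2 * ref) return("A")
  if (ref < 70 && pred < 70) return("A")
  # treatment-reversing errors
  if (ref <= 70 && pred > 180) return("E")
  if (ref >= 180 && pred < 70) return("E")
  # overcorrection zones
  if (ref >= 70 && ref <= 290 && pred > ref + 110) return("C")
  if (ref >= 130 && ref <= 180 && pred < (7 / 5) * ref - 182) return("C")
  # dangerous failure to detect
  if (ref >= 240 && pred >= 70 && pred <= 180) return("D")
  if (ref <= 70 && pred >= 70 && pred <= 180) return("D")
  "B"
}

# Poincare SD1/SD2 via the rotated-scatter definition: SDs of the successive
# IPI pairs projected onto the +/- 45 degree axes.
oracle_poincare <- function(ipi) {
  x <- ipi[-length(ipi)]
  y <- ipi[-1]
  p1 <- (y - x) / sqrt(2)   # minor axis
  p2 <- (y + x) / sqrt(2)   # major axis
  c(sd1 = stats::sd(p1), sd2 = stats::sd(p2))
}

# Exhaustive feature-subset search for small d.
oracle_exhaustive_best <- function(d, fitness) {
  masks <- as.matrix(expand.grid(rep(list(0:1), d)))
  vals <- apply(masks, 1, fitness)
  masks[which.max(vals), ]
}

# Quiet wrapper: pipeline runs emit dropped-record messages by design.
quiet_pipeline <- function(cfg) suppressMessages(run_pipeline(cfg))

# A clean (noise-free, drift-free) record for segmentation tests.
clean_record <- function(hr = 75, duration = 12, fs = 100, bgl = 120,
                         seed = 7, jitter = 0) {
  generate_record(beat = beat_model(heart_rate = hr, hr_jitter_sd = jitter),
                  noise = noise_model(white_sd = 0, drift_amp = 0),
                  bgl = bgl, duration = duration, fs = fs,
                  effect = no_glucose_effect(), seed = seed)
}

rmse_to <- function(a, b) sqrt(mean((a - b)^2))
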