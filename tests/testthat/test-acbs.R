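make_peaks <- function(indices, fs = 100) {
  structure(list(indices = as.integer(indices), fs = fs),
            class = "peak_list")
}

test_that("peak detection finds every clean beat and ignores flat signals", {
  flat <- ppg_signal(rep(1, 500), 100)
  expect_length(detect_peaks(flat)$indices, 0L)

  r <- clean_record(hr = 60, duration = 10, fs = 100)
  p <- detect_peaks(r$signal)
  expect_length(p$indices, 10L)
  # each peak within +/- 20 ms of the ground-truth beat maximum (the local
  # maximum of the clean waveform around each planted beat centre)
  x <- r$signal$samples
  true_max <- vapply(r$beat_times, function(tb) {
    i <- round(tb * 100) + 1L
    win <- max(1, i - 25):min(length(x), i + 25)
    win[which.max(x[win])]
  }, integer(1))
  expect_true(all(abs(p$indices - true_max) <= 2L))
})

test_that("peak detection is amplitude-scale invariant", {
  r <- clean_record(hr = 75, duration = 8)
  p1 <- detect_peaks(r$signal)
  big <- ppg_signal(1000 * r$signal$samples, r$signal$fs)
  p2 <- detect_peaks(big)
  expect_identical(p1$indices, p2$indices)
})

test_that("detected cycle count matches beat count across 40-180 bpm", {
  for (hr in seq(40, 180, by = 20)) {
    r <- clean_record(hr = hr, duration = 12, seed = hr)
    seg <- segment_ppg(r$signal)
    expect_equal(length(seg$peaks$indices), length(r$beat_times),
                 info = paste("hr =", hr))
    expect_equal(length(seg$cycles), length(r$beat_times))
  }
})

test_that("boundaries follow the midpoint / fixed-window rules exactly", {
  b <- boundaries(make_peaks(c(100, 200, 300)), Tf = 50, signal_len = 1000)
  expect_equal(b$starts, c(50L, 150L, 250L))
  expect_equal(b$ends, c(150L, 250L, 350L))
  expect_equal(b$n_peaks, 3L)
  # interior tiling: E_k = St_{k+1}
  expect_equal(b$ends[-length(b$ends)], b$starts[-1])

  b1 <- boundaries(make_peaks(500), Tf = 80, signal_len = 1000)
  expect_equal(b1$starts, 420L)
  expect_equal(b1$ends, 580L)

  # clipping to the signal extent (1-based indices)
  bc <- boundaries(make_peaks(c(10, 200)), Tf = 50, signal_len = 220)
  expect_equal(bc$starts[1], 1L)
  expect_equal(bc$ends[2], 220L)

  # odd midpoints round down
  bo <- boundaries(make_peaks(c(100, 201)), Tf = 10, signal_len = 400)
  expect_equal(bo$ends[1], 150L)

  expect_error(boundaries(make_peaks(integer(0)), 10, 100), "empty")
})

test_that("extracted cycles have length Lg, min 0 and max 1", {
  sig <- ppg_signal(seq(2, 6, length.out = 8), 100)
  b <- boundaries(make_peaks(4), Tf = 3, signal_len = 8)
  cy <- extract_cycles(sig, b, Lg = 8)[[1]]
  expect_equal(cy$values, seq(0, 1, length.out = 8), tolerance = 1e-12)
  expect_equal(cy$raw, sig$samples[1:7])

  r <- clean_record(duration = 10)
  cys <- segment_ppg(r$signal, Lg = 100)$cycles
  for (cy in cys) {
    expect_length(cy$values, 100L)
    expect_equal(min(cy$values), 0)
    expect_equal(max(cy$values), 1)
    expect_true(all(is.finite(cy$values)))
  }

  expect_error(extract_cycles(r$signal, boundaries(make_peaks(50), 10, 1000),
                              Lg = 4), "Lg")
})

test_that("degenerate constant segments yield zeros with a warning", {
  sig <- ppg_signal(rep(2, 20), 100)
  b <- boundaries(make_peaks(10), Tf = 5, signal_len = 20)
  expect_warning(cy <- extract_cycles(sig, b, Lg = 10), "degenerate")
  expect_equal(cy[[1]]$values, rep(0, 10))
})

test_that("resample-then-normalize commutes with normalize-then-resample", {
  # Linear resampling commutes with the affine min-max map exactly whenever
  # the resampling grid retains the original sample points (Lg - 1 a multiple
  # of n - 1); for other grids the two orders agree up to an affine map.
  set.seed(9)
  both_orders <- function(seg, Lg) {
    sig <- ppg_signal(seg, 100)
    b <- boundaries(make_peaks(ceiling(length(seg) / 2)),
                    Tf = ceiling(length(seg) / 2), signal_len = length(seg))
    v1 <- extract_cycles(sig, b, Lg = Lg)[[1]]$values
    nm <- (seg - min(seg)) / (max(seg) - min(seg))
    v2 <- stats::approx(seq_along(nm), nm, n = Lg)$y
    list(v1 = v1, v2 = v2)
  }
  for (i in 1:15) {
    n <- sample(10:40, 1)
    seg <- cumsum(rnorm(n))
    k <- sample(1:3, 1)
    o <- both_orders(seg, Lg = max(8, k * (n - 1) + 1))
    expect_equal(o$v1, o$v2, tolerance = 1e-12)
  }
  for (i in 1:10) {
    seg <- cumsum(rnorm(sample(20:80, 1)))
    o <- both_orders(seg, Lg = sample(8:120, 1))
    expect_gt(stats::cor(o$v1, o$v2), 1 - 1e-12)
  }
})
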