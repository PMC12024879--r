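#' Detect systolic peaks in a (denoised) PPG signal
#'
#' Candidate beats are located where the first derivative is locally maximal
#' (the point of steepest upstroke) and exceeds an adaptive threshold equal to
#' half the rolling 2-second upper quartile of the positive derivative; the
#' threshold scales with the signal, so detection is amplitude-invariant.
#' Candidates closer than the refractory interval `60 / max_hr` seconds keep
#' only the steeper upslope. Each surviving candidate is then snapped to the
#' local signal maximum within the following 0.2 s, so the reported indices
#' sit on the systolic peaks themselves.
#'
#' @param signal A [ppg_signal()], ideally after [denoise()].
#' @param min_hr,max_hr Plausible heart-rate band in beats/min
#'   (`0 < min_hr < max_hr`).
#' @return Object of class `peak_list`: list with `indices` (1-based sample
#'   positions, strictly increasing) and `fs`. A signal shorter than one
#'   maximum beat period yields an empty peak list.
#' @export
detect_peaks <- function(signal, min_hr = 40, max_hr = 180) {
  stopifnot(inherits(signal, "ppg_signal"))
  if (!(min_hr > 0 && min_hr < max_hr))
    stop_arg("need 0 < min_hr < max_hr")
  x <- signal$samples
  fs <- signal$fs
  n <- length(x)
  empty <- structure(list(indices = integer(0), fs = fs), class = "peak_list")
  if (n / fs < 60 / min_hr) return(empty)

  d <- c(diff(x), 0) * fs
  dpos <- pmax(d, 0)
  if (all(dpos == 0)) return(empty)

  # Rolling 2 s upper quartile of the positive derivative, evaluated on
  # anchors every 0.25 s and linearly interpolated.
  half <- round(fs)                      # half-window: 1 s each side
  anchors <- unique(c(seq(1L, n, by = max(1L, round(fs / 4))), n))
  qa <- vapply(anchors, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    stats::quantile(dpos[lo:hi], 0.75, names = FALSE)
  }, numeric(1))
  thr <- 0.5 * stats::approx(anchors, qa, xout = seq_len(n), rule = 2)$y

  # Local maxima of the derivative above threshold.
  cand <- which(d > thr & d >= c(-Inf, d[-n]) & d > c(d[-1], Inf))
  if (!length(cand)) return(empty)

  # Refractory pruning: keep the steeper of any pair closer than 60/max_hr s.
  refr <- round(fs * 60 / max_hr)
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refr) {
      keep <- c(keep, i)
      last <- i
    } else if (d[i] > d[keep[length(keep)]]) {
      keep[length(keep)] <- i
      last <- i
    }
  }

  # Snap each upslope point to the following local signal maximum (<= 0.2 s).
  win <- round(0.2 * fs)
  peaks <- vapply(keep, function(i) {
    hi <- min(n, i + win)
    i - 1L + which.max(x[i:hi])
  }, integer(1))
  peaks <- sort(unique(peaks))
  # A second refractory pass in peak space (snapping can merge candidates).
  if (length(peaks) > 1L) {
    out <- peaks[1L]
    for (p in peaks[-1L]) {
      if (p - out[length(out)] >= refr) out <- c(out, p)
      else if (x[p] > x[out[length(out)]]) out[length(out)] <- p
    }
    peaks <- out
  }
  structure(list(indices = as.integer(peaks), fs = fs), class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("Peak list: %d peaks @ %g Hz\n", length(x$indices), x$fs))
  invisible(x)
}

#' Peak times in seconds
#' @param peaks A `peak_list`.
#' @param t0 Signal start time (s).
#' @return Numeric vector of peak times.
#' @export
peak_times <- function(peaks, t0 = 0) {
  stopifnot(inherits(peaks, "peak_list"))
  t0 + (peaks$indices - 1L) / peaks$fs
}

#' Cycle boundaries from a peak list
#'
#' Interior boundaries are set midway between consecutive peaks:
#' `St_k = floor((Rp_(k-1) + Rp_k) / 2)` and `E_k = floor((Rp_k + Rp_(k+1)) / 2)`
#' (midpoints rounded down, so interior cycles tile the span exactly, with
#' `E_k = St_(k+1)`). The first start and last end, where no neighbouring peak
#' exists, use the fixed window `Tf`: `St_1 = Rp_1 - Tf`, `E_N = Rp_N + Tf`,
#' clipped to the signal extent.
#'
#' @param peaks A `peak_list` with at least one peak.
#' @param Tf Fixed end-window in samples (> 0). `NULL` (default) uses half the
#'   median inter-peak interval, falling back to 0.5 s when fewer than two
#'   peaks are available.
#' @param signal_len Signal length in samples (for clipping).
#' @return Object of class `cycle_boundaries`: list with integer vectors
#'   `starts`, `ends`, plus `Tf` and `n_peaks`.
#' @export
boundaries <- function(peaks, Tf = NULL, signal_len) {
  stopifnot(inherits(peaks, "peak_list"))
  p <- peaks$indices
  if (length(p) == 0L) stop_arg("empty peak list: no cycles to delimit")
  check_scalar(signal_len, "signal_len", positive = TRUE)
  if (is.null(Tf)) {
    Tf <- if (length(p) >= 2L) round(stats::median(diff(p)) / 2)
          else round(0.5 * peaks$fs)
  }
  check_scalar(Tf, "Tf", positive = TRUE)
  N <- length(p)
  mids <- if (N >= 2L) floor((p[-N] + p[-1L]) / 2) else integer(0)
  starts <- c(p[1L] - Tf, mids)
  ends <- c(mids, p[N] + Tf)
  starts <- pmax(as.integer(starts), 1L)
  ends <- pmin(as.integer(ends), as.integer(signal_len))
  structure(list(starts = starts, ends = ends, Tf = as.integer(Tf),
                 n_peaks = N),
            class = "cycle_boundaries")
}

#' Extract, resample and normalize heartbeat cycles
#'
#' Each delimited segment is linearly interpolated to exactly `Lg` samples and
#' min-max scaled to `[0, 1]`. A degenerate segment (max = min) yields an
#' all-zero cycle with a warning.
#'
#' @param signal A [ppg_signal()].
#' @param b A [boundaries()] result.
#' @param Lg Target cycle length in samples (>= 8); default 100.
#' @return List of objects of class `normalized_cycle`, each a list with
#'   `values` (length `Lg`, in `[0, 1]`), `raw` (the untouched segment),
#'   `source_span` (start/end time in s), `Lg`.
#' @export
extract_cycles <- function(signal, b, Lg = 100) {
  stopifnot(inherits(signal, "ppg_signal"), inherits(b, "cycle_boundaries"))
  check_scalar(Lg, "Lg", positive = TRUE)
  if (Lg < 8) stop_arg("`Lg` must be >= 8")
  Lg <- as.integer(Lg)
  x <- signal$samples
  lapply(seq_along(b$starts), function(k) {
    seg <- x[b$starts[k]:b$ends[k]]
    res <- if (length(seg) == 1L) rep(seg, Lg)
           else stats::approx(seq_along(seg), seg, n = Lg)$y
    rng <- range(res)
    if (rng[2] > rng[1]) {
      vals <- (res - rng[1]) / (rng[2] - rng[1])
    } else {
      warning(sprintf("degenerate cycle %d (max = min); returning zeros", k),
              call. = FALSE)
      vals <- rep(0, Lg)
    }
    structure(list(values = vals, raw = seg,
                   source_span = (c(b$starts[k], b$ends[k]) - 1L) / signal$fs +
                     signal$t0,
                   Lg = Lg),
              class = "normalized_cycle")
  })
}

#' Segment a PPG signal into normalized heartbeat cycles
#'
#' Convenience wrapper: [detect_peaks()] then [boundaries()] then
#' [extract_cycles()].
#'
#' @inheritParams detect_peaks
#' @inheritParams extract_cycles
#' @param Tf Fixed end-window in samples, or `NULL` for the adaptive default.
#' @return List with `peaks`, `boundaries`, `cycles`.
#' @export
segment_ppg <- function(signal, Lg = 100, min_hr = 40, max_hr = 180,
                        Tf = NULL) {
  peaks <- detect_peaks(signal, min_hr, max_hr)
  if (length(peaks$indices) == 0L)
    return(list(peaks = peaks, boundaries = NULL, cycles = list()))
  b <- boundaries(peaks, Tf, length(signal$samples))
  list(peaks = peaks, boundaries = b,
       cycles = extract_cycles(signal, b, Lg))
}
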