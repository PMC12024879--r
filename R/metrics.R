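#' Paired reference/predicted glucose readings
#'
#' @param reference,predicted Equal-length numeric vectors in mg/dL; strictly
#'   positive (required by MARD and the error grid).
#' @return Object of class `paired_readings`.
#' @export
paired_readings <- function(reference, predicted) {
  if (length(reference) != length(predicted) || length(reference) < 1L)
    stop_arg("`reference` and `predicted` must have equal length >= 1")
  if (any(!is.finite(reference)) || any(!is.finite(predicted)))
    stop_arg("readings must be finite")
  if (any(reference <= 0) || any(predicted <= 0))
    stop_arg("readings must be positive (mg/dL)")
  structure(list(reference = as.numeric(reference),
                 predicted = as.numeric(predicted)),
            class = "paired_readings")
}

#' Glucose regression metrics
#'
#' `MAE = mean|e|`, `MSE = mean(e^2)`, `RMSE = sqrt(MSE)`,
#' `MARD = 100 * mean(|e| / ref)` (percent), `R2 = 1 - SSE/SST` (`NA` when
#' the reference has zero variance).
#'
#' @param pr A [paired_readings()] (or a list with `reference`/`predicted`).
#' @return Object of class `glucose_metrics`: list with `MAE`, `RMSE`, `MSE`,
#'   `MARD`, `R2`, `n`.
#' @export
regression_metrics <- function(pr) {
  if (!inherits(pr, "paired_readings"))
    pr <- paired_readings(pr$reference, pr$predicted)
  e <- pr$predicted - pr$reference
  mse <- mean(e^2)
  sst <- sum((pr$reference - mean(pr$reference))^2)
  structure(list(MAE = mean(abs(e)), RMSE = sqrt(mse), MSE = mse,
                 MARD = 100 * mean(abs(e) / pr$reference),
                 R2 = if (sst > 0) 1 - sum(e^2) / sst else NA_real_,
                 n = length(e)),
            class = "glucose_metrics")
}

#' @export
print.glucose_metrics <- function(x, ...) {
  cat(sprintf(paste0("Glucose metrics (n = %d):\n",
                     "  MAE  %8.2f mg/dL\n  RMSE %8.2f mg/dL\n",
                     "  MSE  %8.1f mg/dL^2\n  MARD %8.2f %%\n  R2   %8.3f\n"),
              x$n, x$MAE, x$RMSE, x$MSE, x$MARD, x$R2))
  invisible(x)
}

#' Clarke error grid zone assignment
#'
#' Assigns each (reference, predicted) pair in mg/dL to one of the five
#' clinical-risk zones of the Clarke (1987) error grid, using the original
#' piecewise boundaries:
#' \itemize{
#'   \item A: within 20 percent of the reference, or both readings below
#'     70 mg/dL (clinically accurate).
#'   \item E: reference <= 70 with prediction > 180, or reference >= 180
#'     with prediction < 70 (treatment would be reversed).
#'   \item C: overcorrection zones, prediction > reference + 110 for
#'     reference in [70, 290], or prediction < 1.4 * reference - 182 for
#'     reference in [130, 180].
#'   \item D: dangerous failure to detect, reference >= 240 or
#'     reference <= 70 while the prediction sits in the 70-180 band.
#'   \item B: everything else (benign deviations).
#' }
#' Points exactly on a boundary resolve to the less severe zone (rules are
#' applied in the order A, E, C, D, B with the inclusive/strict inequalities
#' chosen accordingly).
#'
#' @param ref,pred Positive numeric vectors (recycled), mg/dL.
#' @return Factor with levels `A`-`E`.
#' @export
clarke_zone <- function(ref, pred) {
  n <- max(length(ref), length(pred))
  ref <- rep_len(as.numeric(ref), n)
  pred <- rep_len(as.numeric(pred), n)
  if (any(!is.finite(ref)) || any(!is.finite(pred)) ||
      any(ref <= 0) || any(pred <= 0))
    stop_arg("readings must be positive and finite")
  zone <- rep(NA_character_, n)
  a <- abs(pred - ref) <= 0.2 * ref | (ref < 70 & pred < 70)
  zone[a] <- "A"
  e <- !a & ((ref <= 70 & pred > 180) | (ref >= 180 & pred < 70))
  zone[e] <- "E"
  cc <- !a & !e & ((ref >= 70 & ref <= 290 & pred > ref + 110) |
                   (ref >= 130 & ref <= 180 & pred < 1.4 * ref - 182))
  zone[cc] <- "C"
  d <- !a & !e & !cc & ((ref >= 240 | ref <= 70) & pred >= 70 & pred <= 180)
  zone[d] <- "D"
  zone[is.na(zone)] <- "B"
  factor(zone, levels = c("A", "B", "C", "D", "E"))
}

#' Clarke error grid report
#'
#' @param pr A [paired_readings()].
#' @return Object of class `ceg_report`: list with `zone` (factor per pair)
#'   and `percent` (named percentages over the five zones, summing to 100).
#' @export
ceg_report <- function(pr) {
  if (!inherits(pr, "paired_readings"))
    pr <- paired_readings(pr$reference, pr$predicted)
  z <- clarke_zone(pr$reference, pr$predicted)
  pct <- 100 * table(z) / length(z)
  structure(list(zone = z,
                 percent = stats::setNames(as.numeric(pct), names(pct))),
            class = "ceg_report")
}

#' @export
print.ceg_report <- function(x, ...) {
  cat(sprintf("Clarke error grid (n = %d):\n", length(x$zone)))
  for (z in names(x$percent))
    cat(sprintf("  Zone %s: %6.2f %%\n", z, x$percent[z]))
  cat(sprintf("  Clinically acceptable (A+B): %.2f %%\n",
              x$percent["A"] + x$percent["B"]))
  invisible(x)
}
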