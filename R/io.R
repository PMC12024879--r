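# File formats: signals as CSV (time_s, amplitude) with a "# fs=..." header
# line; records add a JSON sidecar; feature matrices as CSV with label
# columns bgl_mgdl/class; masks and models as JSON. Numeric values are
# written with 17 significant digits so write -> read round-trips are
# bit-exact.

fmt17 <- function(x) format(x, digits = 17, trim = TRUE)

#' Write / read a PPG signal as CSV
#'
#' The first line is a metadata comment `# fs=<Hz> t0=<s>`, followed by a
#' regular two-column CSV (`time_s`, `amplitude`).
#'
#' @param signal A [ppg_signal()].
#' @param path File path.
#' @return `write_signal_csv` returns `path` invisibly; `read_signal_csv`
#'   returns a [ppg_signal()].
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "ppg_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%s t0=%s", fmt17(signal$fs), fmt17(signal$t0)), con)
  writeLines("time_s,amplitude", con)
  tt <- signal_time(signal)
  writeLines(paste(fmt17(tt), fmt17(signal$samples), sep = ","), con)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  lines <- readLines(path, n = 2L)
  if (!grepl("^# fs=", lines[1L]))
    stop_arg(sprintf("%s line 1: missing '# fs=' metadata header", path))
  fs <- as.numeric(sub("^# fs=([^ ]+).*", "\\1", lines[1L]))
  t0 <- if (grepl("t0=", lines[1L]))
    as.numeric(sub(".*t0=([^ ]+).*", "\\1", lines[1L])) else 0
  if (!is.finite(fs) || fs <= 0)
    stop_arg(sprintf("%s line 1: invalid fs", path))
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "amplitude") %in% names(df)))
    stop_arg(sprintf("%s line 2: expected columns time_s,amplitude", path))
  if (any(is.na(df$amplitude)))
    stop_arg(sprintf("%s line %d: NA amplitude not allowed", path,
                     which(is.na(df$amplitude))[1L] + 2L))
  ppg_signal(df$amplitude, fs, t0)
}

#' Write a synthetic record (CSV signal + JSON sidecar)
#'
#' @param record A `ppg_record`.
#' @param prefix Path prefix; writes `<prefix>.csv` and `<prefix>.json`.
#' @return The two paths, invisibly.
#' @export
write_record <- function(record, prefix) {
  stopifnot(inherits(record, "ppg_record"))
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  write_signal_csv(record$signal, csv)
  jsonlite::write_json(
    list(fs = record$signal$fs, bgl = record$bgl,
         class = as.character(record$glucose_class),
         beat_times = record$beat_times, subject_id = record$subject_id),
    json, auto_unbox = TRUE, digits = I(17))
  invisible(c(csv, json))
}

#' Write / read a labelled feature matrix as CSV
#'
#' Feature columns in their frozen order, then `bgl_mgdl` and `class` label
#' columns when present.
#'
#' @param fm A [feature_matrix()].
#' @param path File path.
#' @return `write_features_csv` returns `path` invisibly; `read_features_csv`
#'   a [feature_matrix()].
#' @export
write_features_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(apply(fm$x, 2, fmt17), stringsAsFactors = FALSE)
  if (nrow(fm$x) == 1L) df <- as.data.frame(t(df))
  names(df) <- colnames(fm$x)
  if (!is.null(fm$bgl)) df$bgl_mgdl <- fmt17(fm$bgl)
  if (!is.null(fm$class)) df$class <- as.character(fm$class)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lab_bgl <- if ("bgl_mgdl" %in% names(df)) as.numeric(df$bgl_mgdl) else NULL
  lab_cls <- if ("class" %in% names(df))
    factor(df$class, levels = c("hypo", "normo", "hyper")) else NULL
  feats <- setdiff(names(df), c("bgl_mgdl", "class"))
  x <- as.matrix(as.data.frame(lapply(df[feats], as.numeric)))
  colnames(x) <- feats
  feature_matrix(x, lab_bgl, lab_cls)
}

#' Write / read a feature mask as JSON
#'
#' The JSON lists each feature name with its bit and a human-readable
#' `selected` / `not selected` status.
#'
#' @param mask A named [feature_mask()].
#' @param path File path.
#' @return `write_mask_json` returns `path` invisibly; `read_mask_json` a
#'   [feature_mask()].
#' @export
write_mask_json <- function(mask, path) {
  stopifnot(inherits(mask, "feature_mask"))
  nms <- names(mask)
  if (is.null(nms)) nms <- sprintf("F%02d", seq_along(mask))
  jsonlite::write_json(
    list(features = nms, bits = as.integer(mask),
         status = ifelse(mask == 1L, "selected", "not selected")),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_json
#' @export
read_mask_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$bits) || is.null(obj$features))
    stop_arg(sprintf("%s: mask JSON needs 'features' and 'bits'", path))
  feature_mask(obj$bits, obj$features)
}

#' Write / read model parameters as JSON
#'
#' Serializes the architecture descriptor and the flat weight vector.
#'
#' @param params A `model_params`.
#' @param path File path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json` a
#'   `model_params`.
#' @export
write_model_json <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  jsonlite::write_json(list(arch = params$arch, theta = params$theta),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$arch) || is.null(obj$theta))
    stop_arg(sprintf("%s: model JSON needs 'arch' and 'theta'", path))
  arch <- obj$arch
  for (nm in c("d_in", "hidden", "n_layers"))
    if (!is.null(arch[[nm]])) arch[[nm]] <- as.integer(arch[[nm]])
  model_params(arch, as.numeric(obj$theta))
}

#' Write paired readings as CSV (`ref_mgdl`, `pred_mgdl`)
#' @param pr A [paired_readings()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pairs_csv <- function(pr, path) {
  stopifnot(inherits(pr, "paired_readings"))
  df <- data.frame(ref_mgdl = fmt17(pr$reference),
                   pred_mgdl = fmt17(pr$predicted))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pairs_csv
#' @export
read_pairs_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("ref_mgdl", "pred_mgdl") %in% names(df)))
    stop_arg(sprintf("%s: expected columns ref_mgdl,pred_mgdl", path))
  paired_readings(as.numeric(df$ref_mgdl), as.numeric(df$pred_mgdl))
}
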