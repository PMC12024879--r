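#' Federated learning configuration
#'
#' Defaults follow the study's federation settings: 5 clients, 20 global
#' communication rounds, Adam with learning rate 0.001, batch size 32,
#' dropout 0.3, 64 hidden units per layer, federated averaging.
#'
#' @param n_clients Number of clients `K` (>= 1).
#' @param rounds Global communication rounds (>= 0; 0 returns the untrained
#'   initial model).
#' @param local_epochs Local epochs per round (>= 1).
#' @param batch_size Mini-batch size.
#' @param learning_rate Step size `eta`.
#' @param optimizer `"adam"` (default) or `"sgd"` (plain gradient descent;
#'   the setting under which the single-step update is exactly
#'   `Mp - eta * grad`).
#' @param lambda_reg,lambda_cls Weights `lambda1`, `lambda2` of the regression
#'   (MSE) and classification (categorical cross-entropy) tasks; both >= 0,
#'   not both 0.
#' @param dropout Dropout rate on hidden activations during training.
#' @param hidden_units Hidden width per layer (mlp).
#' @param n_layers Number of hidden layers (mlp).
#' @param model_kind `"mlp"` (default) or `"linear"` (no hidden layers; used
#'   for closed-form checks).
#' @param standardize Standardize features and BGL targets internally
#'   (z-scores from size-weighted per-client moments); predictions are always
#'   returned in mg/dL.
#' @param seed Integer seed making the full federation reproducible.
#' @return Object of class `fl_config`.
#' @export
fl_config <- function(n_clients = 5, rounds = 20, local_epochs = 2,
                      batch_size = 32, learning_rate = 0.001,
                      optimizer = c("adam", "sgd"),
                      lambda_reg = 1.0, lambda_cls = 1.0,
                      dropout = 0.3, hidden_units = 64, n_layers = 2,
                      model_kind = c("mlp", "linear"),
                      standardize = TRUE, seed = 1) {
  optimizer <- match.arg(optimizer)
  model_kind <- match.arg(model_kind)
  if (n_clients < 1) stop_arg("`n_clients` must be >= 1")
  if (rounds < 0) stop_arg("`rounds` must be >= 0")
  if (local_epochs < 1) stop_arg("`local_epochs` must be >= 1")
  check_scalar(learning_rate, "learning_rate", nonneg = TRUE)
  if (lambda_reg < 0 || lambda_cls < 0 || (lambda_reg == 0 && lambda_cls == 0))
    stop_arg("lambda_reg, lambda_cls must be >= 0 and not both 0")
  if (dropout < 0 || dropout >= 1) stop_arg("`dropout` must be in [0, 1)")
  structure(list(n_clients = as.integer(n_clients),
                 rounds = as.integer(rounds),
                 local_epochs = as.integer(local_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 lambda_reg = lambda_reg, lambda_cls = lambda_cls,
                 dropout = dropout, hidden_units = as.integer(hidden_units),
                 n_layers = as.integer(n_layers), model_kind = model_kind,
                 standardize = isTRUE(standardize), seed = seed),
            class = "fl_config")
}

#' Multi-task loss
#'
#' `Lr` is the mean squared regression error, `Lc` the categorical
#' cross-entropy of the class probabilities, and
#' `Lt = lambda_reg * Lr + lambda_cls * Lc`. Predicted probabilities of zero
#' for a true class are clipped at 1e-12 with a warning.
#'
#' @param pred_bgl,true_bgl Numeric vectors (mg/dL).
#' @param pred_probs Matrix of class probabilities, rows summing to 1.
#' @param true_onehot One-hot matrix of the same shape.
#' @param lambda_reg,lambda_cls Task weights.
#' @return Object of class `loss_report`: list with `Lr`, `Lc`, `Lt`.
#' @export
multitask_loss <- function(pred_bgl, true_bgl, pred_probs, true_onehot,
                           lambda_reg = 1.0, lambda_cls = 1.0) {
  if (length(pred_bgl) != length(true_bgl))
    stop_arg("regression vectors differ in length")
  pred_probs <- as.matrix(pred_probs)
  true_onehot <- as.matrix(true_onehot)
  if (!all(dim(pred_probs) == dim(true_onehot)))
    stop_arg("probability matrices differ in shape")
  if (any(abs(rowSums(pred_probs) - 1) > 1e-6))
    stop_arg("`pred_probs` rows must sum to 1")
  lr <- mean((pred_bgl - true_bgl)^2)
  hit_zero <- any(pred_probs[true_onehot == 1] <= 0)
  if (hit_zero)
    warning("zero predicted probability for a true class; clipped at 1e-12",
            call. = FALSE)
  p <- pmax(pred_probs, 1e-12)
  lc <- -mean(rowSums(true_onehot * log(p)))
  structure(list(Lr = lr, Lc = lc,
                 Lt = lambda_reg * lr + lambda_cls * lc),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("Loss: Lr = %.4g, Lc = %.4g, Lt = %.4g\n", x$Lr, x$Lc, x$Lt))
  invisible(x)
}

#' Parameter delta
#'
#' Element-wise `after - before`; only this difference (never data) needs to
#' cross the client/server boundary.
#'
#' @param before,after `model_params` of identical architecture.
#' @return A `model_params` holding the difference.
#' @export
param_delta <- function(before, after) {
  stopifnot(inherits(before, "model_params"), inherits(after, "model_params"))
  if (!identical(before$arch, after$arch) ||
      length(before$theta) != length(after$theta))
    stop_arg("parameter shapes do not match")
  model_params(before$arch, after$theta - before$theta)
}

#' Apply a parameter delta
#' @param params A `model_params`.
#' @param delta A `model_params` delta of the same architecture.
#' @return Updated `model_params`.
#' @export
apply_delta <- function(params, delta) {
  if (!identical(params$arch, delta$arch))
    stop_arg("parameter shapes do not match")
  model_params(params$arch, params$theta + delta$theta)
}

#' Federated averaging
#'
#' Size-weighted average of client parameter vectors,
#' `sum_i (N_i / N) Mp_i` with `N = sum_i N_i`. This is the only server-side
#' aggregation interface: it accepts model parameters and dataset sizes,
#' never raw data.
#'
#' @param client_params Non-empty list of `model_params` with identical
#'   architectures.
#' @param sizes Positive client dataset sizes `N_i`.
#' @return Aggregated `model_params`.
#' @export
fedavg <- function(client_params, sizes) {
  if (!length(client_params)) stop_arg("no client parameters to aggregate")
  if (length(sizes) != length(client_params) || any(sizes <= 0))
    stop_arg("`sizes` must be positive and match `client_params`")
  arch <- client_params[[1L]]$arch
  len <- length(client_params[[1L]]$theta)
  for (p in client_params)
    if (!identical(p$arch, arch) || length(p$theta) != len)
      stop_arg("client architectures do not match")
  w <- sizes / sum(sizes)
  theta <- Reduce(`+`, Map(function(p, wi) wi * p$theta, client_params, w))
  model_params(arch, theta)
}

# One client's local optimization. `client_index` and `epoch_offset` index
# the global epoch stream so that a K = 1 federation and an uninterrupted
# centralized run consume identical RNG streams (exact with sgd; adam moment
# state restarts at every call, i.e. at each round boundary).
local_train_epochs <- function(params, data, cfg, epochs,
                               client_index = 1L, epoch_offset = 0L) {
  arch <- params$arch
  x <- standardize_x(arch, data$x)
  y_std <- (data$bgl - arch$y_center) / arch$y_scale
  Y <- onehot_classes(data$class)
  n <- nrow(x)
  if (ncol(x) != arch$d_in) stop_arg("feature dimension mismatch")
  theta <- params$theta
  adam_m <- adam_v <- numeric(length(theta))
  adam_t <- 0L
  for (e in seq_len(epochs)) {
    seed_e <- derive_seed(cfg$seed,
                          client_index * 131071L + epoch_offset + e)
    step <- with_seed(seed_e, {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      for (s in starts) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
        w <- unpack_params(model_params(arch, theta))
        fw <- model_forward(w, arch, x[idx, , drop = FALSE], cfg$dropout)
        loss <- internal_loss(fw, y_std[idx], Y[idx, , drop = FALSE],
                              cfg$lambda_reg, cfg$lambda_cls)
        if (!is.finite(loss))
          stop_arg(sprintf(
            "non-finite loss at epoch %d (batch starting %d); check scaling",
            epoch_offset + e, s))
        g <- model_backward(w, arch, fw, x[idx, , drop = FALSE], y_std[idx],
                            Y[idx, , drop = FALSE], cfg$lambda_reg,
                            cfg$lambda_cls, cfg$dropout)
        if (cfg$optimizer == "sgd") {
          theta <- theta - cfg$learning_rate * g
        } else {
          adam_t <- adam_t + 1L
          adam_m <- 0.9 * adam_m + 0.1 * g
          adam_v <- 0.999 * adam_v + 0.001 * g^2
          mhat <- adam_m / (1 - 0.9^adam_t)
          vhat <- adam_v / (1 - 0.999^adam_t)
          theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + 1e-8)
        }
      }
      theta
    })
    theta <- step
  }
  model_params(arch, theta)
}

#' Local client update
#'
#' Runs `cfg$local_epochs` epochs of mini-batch optimization of the combined
#' multi-task loss on one client's data; deterministic given the
#' configuration seed.
#'
#' @param params Current global `model_params`.
#' @param data A labelled [feature_matrix()] (the client's dataset).
#' @param cfg An [fl_config()].
#' @param client_index Client position (seeds its RNG stream).
#' @param epoch_offset Global epoch counter offset (rounds completed so far
#'   times `local_epochs`).
#' @return Updated `model_params`.
#' @export
local_train <- function(params, data, cfg, client_index = 1L,
                        epoch_offset = 0L) {
  stopifnot(inherits(params, "model_params"), inherits(cfg, "fl_config"))
  local_train_epochs(params, data, cfg, cfg$local_epochs, client_index,
                     epoch_offset)
}

# Size-weighted pooled feature/target moments from per-client summary
# statistics (aggregates only; no raw rows cross the boundary).
pooled_moments <- function(clients) {
  ns <- vapply(clients, function(cl) nrow(cl$x), numeric(1))
  N <- sum(ns)
  sx <- Reduce(`+`, lapply(clients, function(cl) colSums(cl$x)))
  sx2 <- Reduce(`+`, lapply(clients, function(cl) colSums(cl$x^2)))
  sy <- sum(vapply(clients, function(cl) sum(cl$bgl), numeric(1)))
  sy2 <- sum(vapply(clients, function(cl) sum(cl$bgl^2), numeric(1)))
  x_center <- sx / N
  x_var <- pmax(sx2 / N - x_center^2, 0)
  x_scale <- sqrt(x_var)
  x_scale[x_scale < 1e-12] <- 1
  y_center <- sy / N
  y_scale <- sqrt(max(sy2 / N - y_center^2, 1e-12))
  list(x_center = x_center, x_scale = x_scale,
       y_center = y_center, y_scale = y_scale)
}

build_arch <- function(d_in, cfg, clients) {
  mom <- if (cfg$standardize) pooled_moments(clients)
         else list(x_center = rep(0, d_in), x_scale = rep(1, d_in),
                   y_center = 0, y_scale = 1)
  list(kind = cfg$model_kind, d_in = as.integer(d_in),
       hidden = cfg$hidden_units, n_layers = cfg$n_layers,
       x_center = as.numeric(mom$x_center),
       x_scale = as.numeric(mom$x_scale),
       y_center = mom$y_center, y_scale = mom$y_scale)
}

apply_mask_fm <- function(fm, mask) {
  if (is.null(mask)) return(fm)
  if (length(mask) != ncol(fm$x)) stop_arg("mask length != feature count")
  feature_matrix(fm$x[, which(mask == 1L), drop = FALSE], fm$bgl, fm$class)
}

#' Federated training loop
#'
#' Broadcasts the global parameters, runs [local_train()] on every client,
#' aggregates the results with [fedavg()], and repeats for `cfg$rounds`
#' rounds. Only parameter vectors cross the client boundary. The returned
#' history holds the size-weighted global training loss `Lt` (on the model's
#' internal standardized scale) after each round.
#'
#' @param clients List of labelled [feature_matrix()] datasets, all with the
#'   same columns.
#' @param cfg An [fl_config()].
#' @param mask Optional [feature_mask()] applied to every client's columns.
#' @return List with `params` (final global `model_params`), `history`
#'   (length `cfg$rounds`), `sizes`.
#' @export
train_federated <- function(clients, cfg = fl_config(), mask = NULL) {
  stopifnot(length(clients) >= 1L, inherits(cfg, "fl_config"))
  clients <- lapply(clients, apply_mask_fm, mask = mask)
  d <- ncol(clients[[1L]]$x)
  for (cl in clients)
    if (ncol(cl$x) != d) stop_arg("clients disagree on feature dimension")
  sizes <- vapply(clients, function(cl) nrow(cl$x), numeric(1))
  arch <- build_arch(d, cfg, clients)
  global <- init_params(arch, derive_seed(cfg$seed, 1L))
  history <- numeric(0)
  for (r in seq_len(cfg$rounds)) {
    updated <- vector("list", length(clients))
    for (i in seq_along(clients)) {
      updated[[i]] <- tryCatch(
        local_train(global, clients[[i]], cfg, client_index = i,
                    epoch_offset = (r - 1L) * cfg$local_epochs),
        error = function(e) stop_arg(sprintf(
          "round %d aborted: client %d failed: %s", r, i, conditionMessage(e))))
    }
    global <- fedavg(updated, sizes)
    history <- c(history, global_train_loss(global, clients, cfg, sizes))
  }
  list(params = global, history = history, sizes = sizes)
}

global_train_loss <- function(params, clients, cfg, sizes) {
  w <- unpack_params(params)
  ls <- vapply(clients, function(cl) {
    x <- standardize_x(params$arch, cl$x)
    fw <- model_forward(w, params$arch, x, 0)
    internal_loss(fw, (cl$bgl - params$arch$y_center) / params$arch$y_scale,
                  onehot_classes(cl$class), cfg$lambda_reg, cfg$lambda_cls)
  }, numeric(1))
  sum(ls * sizes / sum(sizes))
}

#' Centralized training (reference)
#'
#' Uninterrupted mini-batch training on one pooled dataset for
#' `cfg$rounds * cfg$local_epochs` epochs, consuming the same per-epoch RNG
#' stream as a single-client federation; with `optimizer = "sgd"` the two are
#' bit-identical.
#'
#' @param data A labelled [feature_matrix()].
#' @param cfg An [fl_config()].
#' @return List with `params` and `sizes`.
#' @export
train_central <- function(data, cfg = fl_config()) {
  stopifnot(inherits(data, "feature_matrix"), inherits(cfg, "fl_config"))
  arch <- build_arch(ncol(data$x), cfg, list(data))
  params <- init_params(arch, derive_seed(cfg$seed, 1L))
  if (cfg$rounds > 0L)
    params <- local_train_epochs(params, data, cfg,
                                 cfg$rounds * cfg$local_epochs,
                                 client_index = 1L, epoch_offset = 0L)
  list(params = params, sizes = nrow(data$x))
}

#' Predict BGL and glucose class from model parameters
#'
#' Inference is deterministic (dropout disabled). The regression head returns
#' mg/dL; the classification head returns the argmax class and the full
#' softmax probabilities.
#'
#' @param params A `model_params`.
#' @param features Numeric matrix (or [feature_matrix()]) with
#'   `params$arch$d_in` columns.
#' @return List with `bgl` (numeric), `class` (factor hypo/normo/hyper),
#'   `probs` (matrix).
#' @export
predict_params <- function(params, features) {
  stopifnot(inherits(params, "model_params"))
  x <- if (inherits(features, "feature_matrix")) features$x else
    as.matrix(features)
  if (ncol(x) != params$arch$d_in) stop_arg("feature dimension mismatch")
  w <- unpack_params(params)
  fw <- model_forward(w, params$arch, standardize_x(params$arch, x), 0)
  cls <- factor(GLUCOSE_CLASSES[max.col(fw$probs, ties.method = "first")],
                levels = GLUCOSE_CLASSES)
  colnames(fw$probs) <- GLUCOSE_CLASSES
  list(bgl = fw$yhat * params$arch$y_scale + params$arch$y_center,
       class = cls, probs = fw$probs)
}

#' Fit the federated multi-task glucose model
#'
#' The package's central estimator: trains the shared multi-task network
#' (continuous BGL regression plus hypo/normo/hyper classification) across
#' the client datasets by federated averaging, and returns a fitted-model
#' object with the usual methods (`print`, `summary`, `coef`, `predict`,
#' `plot`, `residuals`, `fitted`).
#'
#' @param clients List of labelled [feature_matrix()] datasets (one per
#'   site), or a single `feature_matrix` (degenerate one-client federation).
#' @param config An [fl_config()].
#' @param mask Optional [feature_mask()] restricting the feature columns.
#' @return Object of class `fedglucose`.
#' @export
fedglucose <- function(clients, config = fl_config(), mask = NULL) {
  if (inherits(clients, "feature_matrix")) clients <- list(clients)
  fit <- train_federated(clients, config, mask)
  masked <- lapply(clients, apply_mask_fm, mask = mask)
  pooled_x <- do.call(rbind, lapply(masked, function(cl) cl$x))
  pooled_y <- unlist(lapply(masked, function(cl) cl$bgl))
  pr <- predict_params(fit$params, pooled_x)
  structure(list(params = fit$params, config = config, mask = mask,
                 history = fit$history, sizes = fit$sizes,
                 feature_names = colnames(masked[[1L]]$x),
                 train_fitted = pr$bgl, train_bgl = pooled_y,
                 call = match.call()),
            class = "fedglucose")
}

#' @export
print.fedglucose <- function(x, ...) {
  cat("Federated multi-task glucose model\n")
  cat(sprintf("  clients: %d (N = %d), rounds: %d, model: %s\n",
              length(x$sizes), sum(x$sizes), x$config$rounds,
              x$config$model_kind))
  cat(sprintf("  features (%d): %s\n", length(x$feature_names),
              paste(x$feature_names, collapse = ", ")))
  if (length(x$history))
    cat(sprintf("  final training loss Lt: %.4f\n", utils::tail(x$history, 1)))
  invisible(x)
}

#' @export
summary.fedglucose <- function(object, ...) {
  res <- stats::residuals(object)
  cat("Federated multi-task glucose model\n\n")
  cat(sprintf("Model kind: %s\n", object$config$model_kind))
  cat(sprintf("Clients: %d, sizes: %s\n", length(object$sizes),
              paste(object$sizes, collapse = ", ")))
  cat(sprintf("Parameters: %d\n", length(object$params$theta)))
  cat(sprintf("Training RMSE: %.2f mg/dL, MARD: %.2f%%\n",
              sqrt(mean(res^2)),
              100 * mean(abs(res) / object$train_bgl)))
  invisible(object)
}

#' @export
coef.fedglucose <- function(object, ...) object$params$theta

#' @export
fitted.fedglucose <- function(object, ...) object$train_fitted

#' @export
residuals.fedglucose <- function(object, ...)
  object$train_bgl - object$train_fitted

#' @export
predict.fedglucose <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix"))
    newdata <- apply_mask_fm(newdata, object$mask)
  predict_params(object$params, newdata)
}

#' @export
plot.fedglucose <- function(x, ...) {
  if (!length(x$history)) {
    warning("no training history to plot", call. = FALSE)
    return(invisible(x))
  }
  graphics::plot(seq_along(x$history), x$history, type = "b",
                 xlab = "round", ylab = "global training loss Lt", ...)
  invisible(x)
}
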