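#' Feature mask
#'
#' Binary selector over the feature columns; bit `j = 1` keeps feature `j`.
#'
#' @param bits Vector of 0/1 values.
#' @param names Optional feature names.
#' @return Named integer vector of class `feature_mask`.
#' @export
feature_mask <- function(bits, names = NULL) {
  if (!all(bits %in% c(0, 1))) stop_arg("mask bits must be 0 or 1")
  m <- as.integer(bits)
  if (!is.null(names)) names(m) <- names
  structure(m, class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("Feature mask: %d of %d selected\n", sum(x), length(x)))
  if (!is.null(names(x))) {
    st <- ifelse(x == 1L, "selected", "not selected")
    for (i in seq_along(x)) cat(sprintf("  %-16s %s\n", names(x)[i], st[i]))
  }
  invisible(x)
}

#' Binary PSO configuration
#'
#' Defaults follow the standard constricted settings used for this selection
#' task: 30 particles, inertia weight 0.729, cognitive and social coefficients
#' 1.49, 50 iterations.
#'
#' @param n_particles Swarm size `X` (>= 2).
#' @param inertia Inertia weight `wt` in (0, 1].
#' @param cognitive,social Acceleration coefficients `co1`, `co2` (>= 0).
#' @param max_iter Maximum iterations.
#' @param patience Stop after this many consecutive iterations without
#'   improvement of the global best (>= 1).
#' @param alpha,beta Fitness weights: `Ft = alpha * acc - beta * |mask| / d`.
#' @param velocity_clamp Velocities are clamped to `[-clamp, clamp]` so the
#'   sigmoid transfer never saturates completely.
#' @param seed Integer seed; the whole swarm run is reproducible from it.
#' @return Object of class `pso_config`.
#' @export
pso_config <- function(n_particles = 30, inertia = 0.729,
                       cognitive = 1.49, social = 1.49,
                       max_iter = 50, patience = 10,
                       alpha = 1.0, beta = 0.1,
                       velocity_clamp = 6, seed = 1) {
  if (n_particles < 2) stop_arg("`n_particles` must be >= 2")
  if (!(inertia > 0 && inertia <= 1)) stop_arg("`inertia` must be in (0, 1]")
  if (cognitive < 0 || social < 0) stop_arg("coefficients must be >= 0")
  if (patience < 1) stop_arg("`patience` must be >= 1")
  check_scalar(velocity_clamp, "velocity_clamp", positive = TRUE)
  structure(list(n_particles = as.integer(n_particles), inertia = inertia,
                 cognitive = cognitive, social = social,
                 max_iter = as.integer(max_iter),
                 patience = as.integer(patience),
                 alpha = alpha, beta = beta,
                 velocity_clamp = velocity_clamp, seed = seed),
            class = "pso_config")
}

#' Feature-subset fitness
#'
#' `Ft(mask) = alpha * acc(mask) - beta * |mask| / d`, where `acc` is the
#' evaluator's validation score in `[0, 1]` and the second term penalizes mask
#' size. The empty mask is never a valid model and scores `-Inf`.
#'
#' @param mask A [feature_mask()] (or 0/1 vector).
#' @param evaluator Function mapping a mask to a score in `[0, 1]`.
#' @param alpha,beta Fitness weights.
#' @return Scalar fitness.
#' @export
pso_fitness <- function(mask, evaluator, alpha = 1.0, beta = 0.1) {
  d <- length(mask)
  if (d == 0L) stop_arg("mask has length 0")
  if (sum(mask) == 0L) return(-Inf)
  alpha * evaluator(mask) - beta * sum(mask) / d
}

#' BPSO velocity update
#'
#' `ve <- wt * ve + co1 * ra1 * (pbest - pos) + co2 * ra2 * (gbest - pos)`,
#' with `ra1`, `ra2 ~ U(0, 1)` drawn per dimension and the result clamped to
#' the configured range.
#'
#' @param velocity,position,pbest,gbest Equal-length numeric vectors.
#' @param cfg A [pso_config()].
#' @param ra1,ra2 Optional fixed random vectors (for testing); drawn from the
#'   current RNG by default.
#' @return Updated velocity vector.
#' @export
update_velocity <- function(velocity, position, pbest, gbest, cfg,
                            ra1 = stats::runif(length(velocity)),
                            ra2 = stats::runif(length(velocity))) {
  v <- cfg$inertia * velocity +
    cfg$cognitive * ra1 * (pbest - position) +
    cfg$social * ra2 * (gbest - position)
  pmin(pmax(v, -cfg$velocity_clamp), cfg$velocity_clamp)
}

#' BPSO position update (sigmoid transfer)
#'
#' Bit `j` is set when `sigmoid(ve_j) > ra_j` with fresh `ra_j ~ U(0, 1)`.
#'
#' @param velocity Numeric velocity vector.
#' @param ra Optional fixed random vector (for testing).
#' @return Integer 0/1 vector.
#' @export
update_position <- function(velocity, ra = stats::runif(length(velocity))) {
  as.integer(1 / (1 + exp(-velocity)) > ra)
}

#' Cross-validated mask evaluator
#'
#' Builds the default fitness evaluator: a k-fold cross-validated score of a
#' lightweight model on the selected feature columns. In `"acc"` mode the
#' model is a linear discriminant classifier of the glucose class and the
#' score is classification accuracy; in `"rmse"` mode it is a linear
#' regression of BGL and the score is `max(0, 1 - RMSE / sd(y))`, a negative
#' RMSE rescaled into `[0, 1]`. Features are standardized fold-wise; the fold
#' assignment is fixed at construction so the evaluator is deterministic.
#'
#' @param fm A labelled [feature_matrix()].
#' @param mode `"acc"` (default) or `"rmse"`.
#' @param folds Number of CV folds.
#' @param seed Seed for the fold assignment.
#' @return Function `mask -> score in [0, 1]`.
#' @export
make_cv_evaluator <- function(fm, mode = c("acc", "rmse"), folds = 5,
                              seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  mode <- match.arg(mode)
  x <- fm$x
  n <- nrow(x)
  y <- if (mode == "acc") {
    if (is.null(fm$class)) stop_arg("feature matrix has no class labels")
    fm$class
  } else {
    if (is.null(fm$bgl)) stop_arg("feature matrix has no BGL labels")
    fm$bgl
  }
  fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  function(mask) {
    sel <- which(mask == 1L)
    if (!length(sel)) return(0)
    scores <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      xtr <- x[tr, sel, drop = FALSE]
      xte <- x[!tr, sel, drop = FALSE]
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2, stats::sd)
      sdv[sdv == 0 | !is.finite(sdv)] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
      if (mode == "acc") {
        fit <- tryCatch(
          suppressWarnings(MASS::lda(xtr, grouping = y[tr])),
          error = function(e) NULL)
        if (is.null(fit)) return(0)
        pred <- stats::predict(fit, xte)$class
        mean(pred == y[!tr])
      } else {
        df <- data.frame(y = y[tr], xtr)
        fit <- stats::lm(y ~ ., data = df)
        pred <- stats::predict(fit, newdata = data.frame(xte))
        rmse <- sqrt(mean((pred - y[!tr])^2))
        max(0, 1 - rmse / stats::sd(y))
      }
    }, numeric(1))
    mean(scores)
  }
}

#' Run binary particle swarm optimization for feature selection
#'
#' Iterates the velocity, sigmoid-position, personal-best and global-best
#' updates until `max_iter` iterations or `patience` consecutive iterations
#' without global-best improvement. Fitness values are memoized per mask (the
#' evaluator is deterministic), so repeated visits to the same subset cost
#' nothing.
#'
#' @param features A labelled [feature_matrix()], or `NULL` when a custom
#'   `evaluator` is supplied.
#' @param cfg A [pso_config()].
#' @param evaluator Optional custom evaluator `mask -> [0, 1]`; defaults to
#'   [make_cv_evaluator()] on `features`.
#' @param mode Evaluator mode when the default evaluator is built.
#' @return Object of class `swarm_result`: list with `gbest` (a
#'   [feature_mask()]), `gbest_fitness`, `history` (best fitness after each
#'   iteration, non-decreasing), `n_evaluations`, `cfg`.
#' @export
run_bpso <- function(features = NULL, cfg = pso_config(), evaluator = NULL,
                     mode = c("acc", "rmse")) {
  stopifnot(inherits(cfg, "pso_config"))
  mode <- match.arg(mode)
  if (is.null(evaluator)) {
    if (is.null(features)) stop_arg("supply `features` or `evaluator`")
    evaluator <- make_cv_evaluator(features, mode = mode,
                                   seed = derive_seed(cfg$seed, 999L))
  }
  d <- if (!is.null(features)) ncol(features$x) else {
    ev_d <- attr(evaluator, "d")
    if (is.null(ev_d)) stop_arg("evaluator must carry attr(., \"d\") when no ",
                                "feature matrix is given")
    ev_d
  }
  if (d < 2L) stop_arg("need at least 2 features")
  nms <- if (!is.null(features)) colnames(features$x) else
    attr(evaluator, "names")

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fit_of <- function(bits) {
    key <- paste(bits, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_eval <<- n_eval + 1L
    val <- pso_fitness(bits, evaluator, cfg$alpha, cfg$beta)
    cache[[key]] <- val
    val
  }

  with_seed(cfg$seed, {
    X <- cfg$n_particles
    pos <- matrix(as.integer(stats::runif(X * d) < 0.5), X, d)
    vel <- matrix(stats::runif(X * d, -1, 1), X, d)
    pfit <- apply(pos, 1, fit_of)
    pbest <- pos
    gi <- which.max(pfit)
    gbest <- pbest[gi, ]
    gfit <- pfit[gi]
    history <- numeric(0)
    stall <- 0L
    for (it in seq_len(cfg$max_iter)) {
      improved <- FALSE
      for (i in seq_len(X)) {
        vel[i, ] <- update_velocity(vel[i, ], pos[i, ], pbest[i, ], gbest, cfg)
        pos[i, ] <- update_position(vel[i, ])
        f <- fit_of(pos[i, ])
        if (f > pfit[i]) {
          pfit[i] <- f
          pbest[i, ] <- pos[i, ]
          if (f > gfit) {
            gfit <- f
            gbest <- pos[i, ]
            improved <- TRUE
          }
        }
      }
      history <- c(history, gfit)
      stall <- if (improved) 0L else stall + 1L
      if (stall >= cfg$patience) break
    }
    if (all(is.infinite(pfit)))
      stop_arg("no valid (non-empty) mask was evaluated")
    structure(list(gbest = feature_mask(gbest, nms), gbest_fitness = gfit,
                   history = history, n_evaluations = n_eval, cfg = cfg),
              class = "swarm_result")
  })
}

#' @export
print.swarm_result <- function(x, ...) {
  cat(sprintf(
    "BPSO result: best fitness %.4f after %d iteration(s), %d evaluations\n",
    x$gbest_fitness, length(x$history), x$n_evaluations))
  print(x$gbest)
  invisible(x)
}

#' @export
plot.swarm_result <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "s",
                 xlab = "iteration", ylab = "best fitness", ...)
  invisible(x)
}
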