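# Internal multi-task network: shared hidden layers (mlp) or none (linear),
# with a regression head (standardized BGL) and a 3-class softmax head.

GLUCOSE_CLASSES <- c("hypo", "normo", "hyper")

# Architecture descriptor + flat parameter vector.
model_params <- function(arch, theta) {
  stopifnot(is.numeric(theta))
  if (any(!is.finite(theta))) stop_arg("model parameters must be finite")
  structure(list(arch = arch, theta = as.numeric(theta)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Model parameters: %s, %d weights (input dim %d)\n",
              x$arch$kind, length(x$theta), x$arch$d_in))
  invisible(x)
}

param_shapes <- function(arch) {
  k <- length(GLUCOSE_CLASSES)
  if (arch$kind == "linear") {
    list(wr = c(arch$d_in, 1L), br = c(1L, 1L),
         Wc = c(arch$d_in, k), bc = c(1L, k))
  } else {
    sh <- list(W1 = c(arch$d_in, arch$hidden), b1 = c(1L, arch$hidden))
    if (arch$n_layers >= 2L) {
      for (l in 2:arch$n_layers) {
        sh[[paste0("W", l)]] <- c(arch$hidden, arch$hidden)
        sh[[paste0("b", l)]] <- c(1L, arch$hidden)
      }
    }
    c(sh, list(wr = c(arch$hidden, 1L), br = c(1L, 1L),
               Wc = c(arch$hidden, k), bc = c(1L, k)))
  }
}

unpack_params <- function(p) {
  sh <- param_shapes(p$arch)
  out <- list()
  pos <- 0L
  for (nm in names(sh)) {
    len <- prod(sh[[nm]])
    out[[nm]] <- matrix(p$theta[pos + seq_len(len)], sh[[nm]][1], sh[[nm]][2])
    pos <- pos + len
  }
  stopifnot(pos == length(p$theta))
  out
}

pack_theta <- function(weights, arch) {
  sh <- param_shapes(arch)
  unlist(lapply(names(sh), function(nm) as.numeric(weights[[nm]])),
         use.names = FALSE)
}

# Glorot-uniform initialization, deterministic given seed.
init_params <- function(arch, seed) {
  sh <- param_shapes(arch)
  with_seed(seed, {
    theta <- unlist(lapply(sh, function(s) {
      lim <- sqrt(6 / (s[1] + s[2]))
      stats::runif(prod(s), -lim, lim)
    }), use.names = FALSE)
    model_params(arch, theta)
  })
}

relu <- function(z) pmax(z, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. dropout_p > 0 draws inverted-dropout masks from the current
# RNG (training only). Returns activations needed for backprop.
model_forward <- function(w, arch, X, dropout_p = 0) {
  if (arch$kind == "linear") {
    yhat <- as.numeric(X %*% w$wr) + w$br[1, 1]
    logits <- sweep(X %*% w$Wc, 2, -as.numeric(w$bc), "-")
    return(list(yhat = yhat, probs = softmax_rows(logits), H = list(X),
                Z = list(), M = list()))
  }
  L <- arch$n_layers
  H <- vector("list", L + 1L)
  Z <- vector("list", L)
  M <- vector("list", L)
  H[[1]] <- X
  for (l in seq_len(L)) {
    W <- w[[paste0("W", l)]]
    b <- as.numeric(w[[paste0("b", l)]])
    Z[[l]] <- sweep(H[[l]] %*% W, 2, -b, "-")
    A <- relu(Z[[l]])
    if (dropout_p > 0) {
      M[[l]] <- matrix(stats::runif(length(A)) >= dropout_p,
                       nrow(A), ncol(A)) / (1 - dropout_p)
      A <- A * M[[l]]
    }
    H[[l + 1L]] <- A
  }
  top <- H[[L + 1L]]
  yhat <- as.numeric(top %*% w$wr) + w$br[1, 1]
  logits <- sweep(top %*% w$Wc, 2, -as.numeric(w$bc), "-")
  list(yhat = yhat, probs = softmax_rows(logits), H = H, Z = Z, M = M)
}

# Gradient of Lt = l1 * mean((yhat - y)^2) + l2 * CCE wrt all parameters,
# returned as a flat vector in the canonical layout.
model_backward <- function(w, arch, fw, X, y_std, Y_onehot, l1, l2,
                           dropout_p = 0) {
  n <- nrow(X)
  dy <- 2 * l1 * (fw$yhat - y_std) / n
  dlog <- l2 * (fw$probs - Y_onehot) / n
  g <- list()
  if (arch$kind == "linear") {
    g$wr <- crossprod(X, dy)
    g$br <- matrix(sum(dy), 1, 1)
    g$Wc <- crossprod(X, dlog)
    g$bc <- matrix(colSums(dlog), 1)
    return(pack_theta(g, arch))
  }
  L <- arch$n_layers
  top <- fw$H[[L + 1L]]
  g$wr <- crossprod(top, dy)
  g$br <- matrix(sum(dy), 1, 1)
  g$Wc <- crossprod(top, dlog)
  g$bc <- matrix(colSums(dlog), 1)
  dA <- outer(dy, as.numeric(w$wr)) + dlog %*% t(w$Wc)
  for (l in L:1) {
    if (dropout_p > 0) dA <- dA * fw$M[[l]]
    dZ <- dA * (fw$Z[[l]] > 0)
    g[[paste0("W", l)]] <- crossprod(fw$H[[l]], dZ)
    g[[paste0("b", l)]] <- matrix(colSums(dZ), 1)
    if (l > 1L) dA <- dZ %*% t(w[[paste0("W", l)]])
  }
  pack_theta(g, arch)
}

# Internal loss on the standardized scale (the optimized objective).
internal_loss <- function(fw, y_std, Y_onehot, l1, l2) {
  lr <- mean((fw$yhat - y_std)^2)
  p <- pmax(fw$probs, 1e-12)
  lc <- -mean(rowSums(Y_onehot * log(p)))
  l1 * lr + l2 * lc
}

onehot_classes <- function(cls) {
  cls <- factor(as.character(cls), levels = GLUCOSE_CLASSES)
  if (any(is.na(cls))) stop_arg("unknown glucose class label")
  Y <- matrix(0, length(cls), length(GLUCOSE_CLASSES))
  Y[cbind(seq_along(cls), as.integer(cls))] <- 1
  Y
}

# Standardize features/targets with the model's stored statistics.
standardize_x <- function(arch, x) {
  sweep(sweep(x, 2, arch$x_center), 2, arch$x_scale, "/")
}
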