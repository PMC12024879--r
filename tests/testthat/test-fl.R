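# Small labelled datasets for federation tests.
toy_clients <- function(k = 2, n = 40, d = 3, seed = 1) {
  set.seed(seed)
  lapply(seq_len(k), function(i) {
    x <- matrix(rnorm(n * d), n, d)
    colnames(x) <- paste0("f", seq_len(d))
    y <- pmax(50, 150 + 40 * x[, 1] + rnorm(n, 0, 5))
    feature_matrix(x, y, label_class(y))
  })
}

test_that("multi-task loss combines MSE and cross-entropy as specified", {
  oh <- function(i) {
    m <- matrix(0, length(i), 3)
    m[cbind(seq_along(i), i)] <- 1
    m
  }
  # perfect regression, classification off
  l <- multitask_loss(c(100, 200), c(100, 200), oh(c(1, 2)), oh(c(1, 2)),
                      lambda_cls = 0)
  expect_equal(l$Lt, 0)
  # perfectly confident correct classification
  l2 <- multitask_loss(0, 0, matrix(c(0, 1, 0), 1), matrix(c(0, 1, 0), 1))
  expect_equal(l2$Lc, 0)
  # true 100, predicted 110 -> Lt = 100 mg/dL^2 at lambda = (1, 0)
  l3 <- multitask_loss(110, 100, matrix(1 / 3, 1, 3), oh(1), 1, 0)
  expect_equal(l3$Lr, 100)
  expect_equal(l3$Lt, 100)
  # zero probability for the true class is clipped with a warning
  expect_warning(
    l4 <- multitask_loss(0, 0, matrix(c(1, 0, 0), 1), matrix(c(0, 1, 0), 1)),
    "clipped")
  expect_equal(l4$Lc, -log(1e-12))
  expect_error(multitask_loss(1, c(1, 2), oh(1), oh(1)), "length")
  expect_error(multitask_loss(1, 1, matrix(c(2, 2, 2), 1), oh(1)), "sum to 1")
})

test_that("parameter deltas obey the exchange identities", {
  arch <- list(kind = "test")
  a <- ppgfl:::model_params(arch, c(1, 2, 3))
  b <- ppgfl:::model_params(arch, c(2, 0, 3.5))
  expect_equal(param_delta(a, a)$theta, c(0, 0, 0))
  expect_equal(param_delta(a, b)$theta, -param_delta(b, a)$theta)
  expect_equal(apply_delta(a, param_delta(a, b))$theta, b$theta)
  expect_error(param_delta(a, ppgfl:::model_params(arch, 1:2)), "shapes")
})

test_that("fedavg is the size-weighted average with conservation", {
  arch <- list(kind = "test")
  p1 <- ppgfl:::model_params(arch, c(1, 1))
  p3 <- ppgfl:::model_params(arch, c(3, 3))
  expect_equal(fedavg(list(p1, p3), c(100, 300))$theta, c(2.5, 2.5))
  expect_equal(fedavg(list(p1, p3), c(7, 7))$theta, c(2, 2))
  expect_equal(fedavg(list(p3), 5)$theta, p3$theta)
  # aggregate of identical vectors is that vector, to machine precision
  expect_equal(fedavg(list(p1, p1, p1), c(1, 2, 3))$theta, p1$theta,
               tolerance = 1e-15)
  expect_error(fedavg(list(), numeric(0)), "no client")
  expect_error(fedavg(list(p1, p3), c(1, -1)), "positive")
})

test_that("the server aggregation interface accepts only params and sizes", {
  expect_identical(names(formals(fedavg)), c("client_params", "sizes"))
})

test_that("zero learning rate and fixed seeds give exact reproducibility", {
  cl <- toy_clients(1)
  cfg0 <- fl_config(rounds = 2, learning_rate = 0, optimizer = "sgd",
                    model_kind = "linear", seed = 5)
  fit0 <- train_federated(cl, cfg0)
  init <- train_federated(cl, fl_config(rounds = 0, model_kind = "linear",
                                        seed = 5))
  expect_identical(fit0$params$theta, init$params$theta)

  cfg <- fl_config(rounds = 2, local_epochs = 2, seed = 6)
  f1 <- train_federated(toy_clients(2), cfg)
  f2 <- train_federated(toy_clients(2), cfg)
  expect_identical(f1$params$theta, f2$params$theta)
  expect_length(f1$history, 2L)
})

test_that("full-batch training of the convex linear task strictly descends", {
  cl <- toy_clients(1, n = 60)[[1]]
  cfg <- fl_config(rounds = 1, local_epochs = 1, batch_size = 60,
                   optimizer = "sgd", learning_rate = 0.05, lambda_cls = 0,
                   dropout = 0, model_kind = "linear", seed = 2)
  params <- train_federated(list(cl), fl_config(rounds = 0,
                                                model_kind = "linear",
                                                lambda_cls = 0, dropout = 0,
                                                seed = 2))$params
  losses <- numeric(10)
  for (i in 1:10) {
    params <- local_train(params, cl, cfg, client_index = 1L,
                          epoch_offset = i - 1L)
    pred <- predict_params(params, cl$x)
    losses[i] <- mean((pred$bgl - cl$bgl)^2)
  }
  expect_true(all(diff(losses) < 0))
})

test_that("a one-client federation equals centralized training bit-for-bit", {
  cl <- toy_clients(1, n = 50)
  cfg <- fl_config(rounds = 4, local_epochs = 2, optimizer = "sgd",
                   learning_rate = 0.01, dropout = 0.3, seed = 11)
  fed <- train_federated(cl, cfg)
  cen <- train_central(cl[[1]], cfg)
  expect_identical(fed$params$theta, cen$params$theta)
})

test_that("single-round full-batch SGD matches the pooled gradient step", {
  set.seed(1)
  n <- 40
  d <- 3
  xs <- matrix(rnorm(2 * n * d), 2 * n, d)
  colnames(xs) <- paste0("f", 1:d)
  y <- pmax(50, rowSums(xs) * 5 + 150 + rnorm(2 * n))
  cls <- label_class(y)
  cl <- list(feature_matrix(xs[1:n, ], y[1:n], cls[1:n]),
             feature_matrix(xs[(n + 1):(2 * n), ], y[(n + 1):(2 * n)],
                            cls[(n + 1):(2 * n)]))
  eta <- 1e-4
  cfg <- fl_config(rounds = 1, local_epochs = 1, batch_size = n,
                   optimizer = "sgd", learning_rate = eta, lambda_cls = 0,
                   dropout = 0, model_kind = "linear", standardize = FALSE,
                   seed = 4)
  th0 <- train_federated(cl, fl_config(rounds = 0, model_kind = "linear",
                                       standardize = FALSE,
                                       seed = 4))$params$theta
  out <- train_federated(cl, cfg)$params$theta

  # closed form: theta - eta * mean_i (2 / N_i) X_i' r_i (regression head
  # only; classification gradients vanish at lambda_cls = 0)
  wr <- th0[1:d]
  br <- th0[d + 1]
  r <- as.numeric(xs %*% wr) + br - y
  gw <- (2 * crossprod(xs[1:n, ], r[1:n]) / n +
           2 * crossprod(xs[(n + 1):(2 * n), ], r[(n + 1):(2 * n)]) / n) / 2
  gb <- (2 * sum(r[1:n]) / n + 2 * sum(r[(n + 1):(2 * n)]) / n) / 2
  expect_lt(max(abs(out[1:d] - (wr - eta * as.numeric(gw)))), 1e-8)
  expect_lt(abs(out[d + 1] - (br - eta * gb)), 1e-8)
  expect_equal(out[-(1:(d + 1))], th0[-(1:(d + 1))])
})

test_that("prediction is deterministic and argmaxes the class head", {
  cl <- toy_clients(2)
  m <- fedglucose(cl, fl_config(rounds = 3, seed = 8))
  p1 <- predict(m, cl[[1]])
  p2 <- predict(m, cl[[1]])
  expect_identical(p1, p2)  # dropout disabled at inference
  expect_true(all(abs(rowSums(p1$probs) - 1) < 1e-9))
  expect_identical(as.character(p1$class),
                   colnames(p1$probs)[max.col(p1$probs, "first")])
  expect_error(predict_params(m$params, matrix(0, 2, 7)), "dimension")
})

test_that("the fitted model beats the predict-the-mean baseline", {
  clients <- lapply(1:3, function(i)
    simulate_feature_matrix(n = 120, seed = 20 + i))
  m <- fedglucose(clients, fl_config(rounds = 12, local_epochs = 2,
                                     learning_rate = 0.005, seed = 3))
  te <- simulate_feature_matrix(n = 150, seed = 77)
  p <- predict(m, te)
  rmse <- sqrt(mean((p$bgl - te$bgl)^2))
  base <- sqrt(mean((te$bgl - mean(unlist(lapply(clients, `[[`, "bgl"))))^2))
  expect_lt(rmse, base)
  expect_length(m$history, 12L)
  expect_true(all(is.finite(coef(m))))
  expect_equal(residuals(m), m$train_bgl - fitted(m))
})

test_that("a zero-round federation still yields a usable (untrained) model", {
  cl <- toy_clients(2)
  m <- fedglucose(cl, fl_config(rounds = 0, seed = 1))
  expect_length(m$history, 0L)
  p <- predict(m, cl[[1]])
  expect_true(all(is.finite(p$bgl)))
})
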