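#' Pipeline configuration
#'
#' Builds the full multi-stage configuration with study defaults; any nested
#' entry can be overridden. Stages: `synth` (record generation across
#' clients), `preprocess` (CWT denoise), `segment` (cycle extraction),
#' `pso` (feature selection), `fl` (federated training), `evaluate`
#' (held-out metrics and error grid).
#'
#' @param ... Named overrides merged (recursively) over the defaults, e.g.
#'   `fl = list(rounds = 5)`.
#' @param seed Global seed; every stage derives its randomness from it.
#' @param out_dir Output directory for artifacts (`NULL` = don't write).
#' @return Object of class `pipeline_config` (a nested list).
#' @export
pipeline_config <- function(..., seed = 1, out_dir = NULL) {
  defaults <- list(
    seed = seed,
    out_dir = out_dir,
    synth = list(n_clients = 5, records_per_client = 100, duration = 10,
                 fs = 100, heterogeneity = 0.5, bgl_range = c(50, 300),
                 thresholds = c(70, 180),
                 heart_rate = 75, hr_jitter_sd = 0.01,
                 white_sd = 0.05, drift_amp = 0.3, drift_freq = 0.05,
                 artifact_rate = 0, artifact_amp = 1,
                 effect = "default"),
    preprocess = list(method = "denoise", drift_cutoff = 0.5,
                      fmin = 0.05, fmax = 8, n_scales = 48),
    segment = list(Lg = 100, min_hr = 40, max_hr = 180),
    pso = list(enabled = TRUE, n_particles = 30, max_iter = 50,
               patience = 10, mode = "acc", alpha = 1, beta = 0.1,
               inertia = 0.729, cognitive = 1.49, social = 1.49),
    fl = list(rounds = 20, local_epochs = 2, batch_size = 32,
              learning_rate = 0.001, optimizer = "adam", dropout = 0.3,
              hidden_units = 64, n_layers = 2, model_kind = "mlp",
              lambda_reg = 1, lambda_cls = 1, standardize = TRUE),
    evaluate = list(test_fraction = 0.3)
  )
  over <- list(...)
  cfg <- defaults
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  cfg$seed <- seed
  cfg$out_dir <- out_dir
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file; keys mirror [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!is.list(obj)) stop_arg("config file must hold a mapping")
  seed <- if (!is.null(obj$seed)) obj$seed else 1
  out_dir <- obj$out_dir
  obj$seed <- NULL
  obj$out_dir <- NULL
  do.call(pipeline_config, c(obj, list(seed = seed, out_dir = out_dir)))
}

#' Run the full synthetic federated glucose-monitoring study
#'
#' Executes simulate -> denoise -> segment -> features -> select -> fedtrain
#' -> evaluate under a single global seed. A per-client test fraction is held
#' out before feature selection and training; metrics and the Clarke error
#' grid are computed on the pooled held-out pairs. Predicted BGLs are clamped
#' to the physically plausible 1-1000 mg/dL range before error-grid scoring.
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Print per-stage progress.
#' @return Object of class `run_manifest`: per-stage record counts and
#'   wall-clock seconds, plus `result` holding the fitted model, mask, test
#'   metrics (`glucose_metrics`), error-grid report, classification accuracy
#'   and the predict-the-mean baseline RMSE. If a stage fails, the manifest
#'   records the stages completed so far with `failed_stage` and `error` set
#'   and `result = NULL`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stages <- list()
  current_stage <- "simulate"
  note <- function(...) if (verbose) message(sprintf(...))
  tick <- function(name, n_in, n_out, t0) {
    stages[[name]] <<- list(n_in = n_in, n_out = n_out,
                            seconds = round(as.numeric(Sys.time() - t0), 3))
  }
  # A failing stage yields a partial manifest naming the stage, not a bare
  # error.
  tryCatch(
    run_pipeline_stages(cfg, note, tick, function(s) current_stage <<- s,
                        function() stages),
    error = function(e) {
      structure(list(stages = stages, seed = cfg$seed, result = NULL,
                     failed_stage = current_stage,
                     error = conditionMessage(e)),
                class = "run_manifest")
    })
}

run_pipeline_stages <- function(cfg, note, tick, enter, get_stages) {
  enter("simulate")

  # --- simulate -------------------------------------------------------------
  t0 <- Sys.time()
  sy <- cfg$synth
  effect <- if (identical(sy$effect, "default")) glucose_effect()
            else if (identical(sy$effect, "none")) no_glucose_effect()
            else do.call(glucose_effect, sy$effect)
  clients <- generate_federated_datasets(
    n_clients = sy$n_clients, records_per_client = sy$records_per_client,
    effect = effect, heterogeneity = sy$heterogeneity,
    seed = derive_seed(cfg$seed, 11L),
    beat = beat_model(heart_rate = sy$heart_rate,
                      hr_jitter_sd = sy$hr_jitter_sd),
    noise = noise_model(white_sd = sy$white_sd, drift_amp = sy$drift_amp,
                        drift_freq = sy$drift_freq,
                        artifact_rate = sy$artifact_rate,
                        artifact_amp = sy$artifact_amp),
    duration = sy$duration, fs = sy$fs, bgl_range = sy$bgl_range,
    thresholds = sy$thresholds)
  n_rec <- sum(vapply(clients, function(cl) length(cl$records), numeric(1)))
  tick("simulate", n_rec, n_rec, t0)
  note("simulate: %d records over %d clients", n_rec, length(clients))

  # --- denoise + segment + features ----------------------------------------
  enter("features")
  t0 <- Sys.time()
  pp <- cfg$preprocess
  do_dn <- identical(pp$method, "denoise")
  spec <- wavelet_spec("mexican_hat")
  grid <- if (do_dn)
    default_scale_grid(pp$fmin, pp$fmax, pp$n_scales, spec) else NULL
  feats <- lapply(clients, function(cl) {
    fm <- if (do_dn) {
      build_feature_matrix(cl$records, Lg = cfg$segment$Lg,
                           min_hr = cfg$segment$min_hr,
                           max_hr = cfg$segment$max_hr,
                           preprocess = "denoise", spec = spec, grid = grid,
                           drift_cutoff = pp$drift_cutoff)
    } else {
      build_feature_matrix(cl$records, Lg = cfg$segment$Lg,
                           min_hr = cfg$segment$min_hr,
                           max_hr = cfg$segment$max_hr, preprocess = "none")
    }
    attr(fm, "client_id") <- cl$client_id
    fm
  })
  n_rows <- sum(vapply(feats, function(f) nrow(f$x), numeric(1)))
  tick("features", n_rec, n_rows, t0)
  note("features: %d/%d records yielded complete feature rows", n_rows, n_rec)

  # --- train/test split (per client) ---------------------------------------
  enter("split")
  t0 <- Sys.time()
  split <- lapply(seq_along(feats), function(i) {
    fm <- feats[[i]]
    n <- nrow(fm$x)
    n_te <- max(1L, round(cfg$evaluate$test_fraction * n))
    te <- with_seed(derive_seed(cfg$seed, 50L + i), sample.int(n, n_te))
    list(train = feature_matrix(fm$x[-te, , drop = FALSE],
                                fm$bgl[-te], fm$class[-te]),
         test = feature_matrix(fm$x[te, , drop = FALSE],
                               fm$bgl[te], fm$class[te]))
  })
  train_clients <- lapply(split, `[[`, "train")
  test_pool_x <- do.call(rbind, lapply(split, function(s) s$test$x))
  test_bgl <- unlist(lapply(split, function(s) s$test$bgl))
  test_class <- factor(unlist(lapply(split, function(s)
    as.character(s$test$class))), levels = c("hypo", "normo", "hyper"))
  tick("split", n_rows, n_rows, t0)

  # --- feature selection ----------------------------------------------------
  enter("select")
  t0 <- Sys.time()
  if (isTRUE(cfg$pso$enabled)) {
    pooled_train <- feature_matrix(
      do.call(rbind, lapply(train_clients, function(s) s$x)),
      unlist(lapply(train_clients, function(s) s$bgl)),
      factor(unlist(lapply(train_clients, function(s) as.character(s$class))),
             levels = c("hypo", "normo", "hyper")))
    swarm <- run_bpso(pooled_train,
                      pso_config(n_particles = cfg$pso$n_particles,
                                 max_iter = cfg$pso$max_iter,
                                 patience = cfg$pso$patience,
                                 alpha = cfg$pso$alpha, beta = cfg$pso$beta,
                                 inertia = cfg$pso$inertia,
                                 cognitive = cfg$pso$cognitive,
                                 social = cfg$pso$social,
                                 seed = derive_seed(cfg$seed, 23L)),
                      mode = cfg$pso$mode)
    mask <- swarm$gbest
  } else {
    swarm <- NULL
    mask <- feature_mask(rep(1L, ncol(feats[[1L]]$x)),
                         colnames(feats[[1L]]$x))
  }
  tick("select", ncol(feats[[1L]]$x), sum(mask), t0)
  note("select: %d of %d features", sum(mask), length(mask))

  # --- federated training ----------------------------------------------------
  enter("fedtrain")
  t0 <- Sys.time()
  flc <- cfg$fl
  model <- fedglucose(train_clients,
                      fl_config(n_clients = length(train_clients),
                                rounds = flc$rounds,
                                local_epochs = flc$local_epochs,
                                batch_size = flc$batch_size,
                                learning_rate = flc$learning_rate,
                                optimizer = flc$optimizer,
                                lambda_reg = flc$lambda_reg,
                                lambda_cls = flc$lambda_cls,
                                dropout = flc$dropout,
                                hidden_units = flc$hidden_units,
                                n_layers = flc$n_layers,
                                model_kind = flc$model_kind,
                                standardize = flc$standardize,
                                seed = derive_seed(cfg$seed, 37L)),
                      mask = mask)
  tick("fedtrain", sum(model$sizes), length(model$params$theta), t0)

  # --- evaluate ---------------------------------------------------------------
  enter("evaluate")
  t0 <- Sys.time()
  pred <- predict_params(model$params,
                         test_pool_x[, which(mask == 1L), drop = FALSE])
  pred_bgl <- pmin(pmax(pred$bgl, 1), 1000)
  pairs <- paired_readings(test_bgl, pred_bgl)
  metrics <- regression_metrics(pairs)
  ceg <- ceg_report(pairs)
  acc <- mean(pred$class == test_class)
  train_mean <- mean(unlist(lapply(train_clients, function(s) s$bgl)))
  baseline_rmse <- sqrt(mean((test_bgl - train_mean)^2))
  tick("evaluate", length(test_bgl), length(test_bgl), t0)

  result <- list(model = model, mask = mask, swarm = swarm,
                 pairs = pairs, metrics = metrics, ceg = ceg,
                 class_accuracy = acc, baseline_rmse = baseline_rmse,
                 n_test = length(test_bgl))

  # --- artifacts --------------------------------------------------------------
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mask_json(mask, file.path(cfg$out_dir, "mask.json"))
    write_model_json(model$params, file.path(cfg$out_dir, "model.json"))
    write_pairs_csv(pairs, file.path(cfg$out_dir, "pairs.csv"))
    utils::write.csv(data.frame(round = seq_along(model$history),
                                loss = model$history),
                     file.path(cfg$out_dir, "history.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(metrics = unclass(metrics)[c("MAE", "RMSE", "MSE", "MARD", "R2")],
           ceg_percent = as.list(ceg$percent),
           class_accuracy = acc, baseline_rmse = baseline_rmse,
           n_test = length(test_bgl), seed = cfg$seed),
      file.path(cfg$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }

  structure(list(stages = get_stages(), seed = cfg$seed, result = result),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %s)\n", format(x$seed)))
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-9s in %5d  out %5d  %7.2fs\n", nm, s$n_in, s$n_out,
                s$seconds))
  }
  if (!is.null(x$failed_stage)) {
    cat(sprintf("FAILED at stage '%s': %s\n", x$failed_stage, x$error))
    return(invisible(x))
  }
  cat(sprintf("Test RMSE %.2f mg/dL (baseline %.2f), MARD %.2f%%, A+B %.1f%%\n",
              x$result$metrics$RMSE, x$result$baseline_rmse,
              x$result$metrics$MARD,
              x$result$ceg$percent["A"] + x$result$ceg$percent["B"]))
  invisible(x)
}
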