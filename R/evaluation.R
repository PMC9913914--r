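# Masked RMSE, walk-forward test evaluation and feature-configuration
# comparison.

#' Masked root-mean-squared error
#'
#' RMSE over evaluable positions only: within test data, only samples
#' the sensor actually recorded are compared, never imputed ones.
#' Masked entries may hold any value (including `NA`) without affecting
#' the result.
#'
#' @param predictions,actuals Numeric vectors/matrices of equal shape.
#' @param mask Logical, same shape; `TRUE` marks evaluable
#'   (sensor-recorded) positions. Default: all evaluable.
#' @return RMSE in mg/dL.
#' @export
rmse_masked <- function(predictions, actuals, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(actuals))
  if (length(predictions) != length(actuals) ||
      length(mask) != length(actuals)) {
    stop("predictions, actuals and mask must have equal shape", call. = FALSE)
  }
  m <- as.logical(mask)
  if (!any(m)) {
    stop("no evaluable positions: every target is masked", call. = FALSE)
  }
  sqrt(mean((as.numeric(predictions)[m] - as.numeric(actuals)[m])^2))
}

#' Walk-forward evaluation on a test segment
#'
#' Applies a frozen trained model to consecutive non-overlapping test
#' windows (stride = history length, no retraining between steps),
#' pools all horizon positions of all windows, and computes RMSE with
#' imputed targets masked out.
#'
#' @param model A trained `forecaster` (with standardizer attached).
#' @param test_matrix Feature matrix of the test segment
#'   (samples x channels, raw scale).
#' @param test_target Test CGM [sampled_series()] (provenance drives the
#'   mask) or numeric vector.
#' @param spec A [window_spec()]; its horizon must match the model.
#' @param patient_id,config_name Labels carried into the report.
#' @param predict_fn Optional replacement predictor,
#'   `function(inputs_array) -> matrix [examples, horizon]`, e.g. a
#'   persistence baseline or an oracle; when given, `model` may be
#'   `NULL`.
#' @return An object of class `eval_report`: `rmse`, `n_evaluated`,
#'   `n_masked`, `per_example_rmse`, `per_step_rmse`, `predictions`,
#'   `actuals`, `mask`.
#' @export
walk_forward_evaluate <- function(model, test_matrix, test_target,
                                  spec = window_spec(),
                                  patient_id = NA_character_,
                                  config_name = NA_character_,
                                  predict_fn = NULL) {
  stopifnot(inherits(spec, "window_spec"))
  if (is.null(predict_fn)) {
    stopifnot(inherits(model, "forecaster"))
    if (spec$horizon_len != model$spec$horizon_len) {
      stop("window horizon (", spec$horizon_len, ") does not match the model ",
           "head (", model$spec$horizon_len, ")", call. = FALSE)
    }
    predict_fn <- function(inputs) predict_horizon(model, inputs)
  }
  wins <- make_windows(test_matrix, test_target, spec)
  preds <- predict_fn(wins$inputs)
  mask <- wins$mask & is.finite(wins$outputs)
  rmse <- rmse_masked(preds, wins$outputs, mask)
  per_example <- vapply(seq_len(nrow(preds)), function(e) {
    if (any(mask[e, ])) rmse_masked(preds[e, ], wins$outputs[e, ], mask[e, ])
    else NA_real_
  }, numeric(1))
  per_step <- vapply(seq_len(ncol(preds)), function(s) {
    if (any(mask[, s])) rmse_masked(preds[, s], wins$outputs[, s], mask[, s])
    else NA_real_
  }, numeric(1))
  structure(list(
    patient_id = patient_id, config_name = config_name,
    horizon_mins = horizon_minutes(spec),
    rmse = rmse,
    n_examples = nrow(preds),
    n_evaluated = sum(mask),
    n_masked = length(mask) - sum(mask),
    per_example_rmse = per_example, per_step_rmse = per_step,
    predictions = preds, actuals = wins$outputs, mask = mask
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> patient=%s config=%s PH=%d min: RMSE %.2f mg/dL over %d targets (%d masked)\n",
    x$patient_id, x$config_name, x$horizon_mins, x$rmse, x$n_evaluated,
    x$n_masked))
  invisible(x)
}

#' Run the full pipeline for one configuration
#'
#' Preprocess (if needed) -> feature assembly -> rolling-origin final
#' train/validation split -> standardize (fit on training rows only) ->
#' window -> train -> walk-forward evaluation on the test segment.
#'
#' @param record A [patient_record()].
#' @param config A [feature_config()] or name.
#' @param win A [window_spec()].
#' @param mspec A [model_spec()] (its `horizon_len` is overridden by
#'   `win`).
#' @param tspec A [training_spec()].
#' @param carb_params,insulin_params Kinetics parameters.
#' @param k_splits Rolling-origin split count used to size the
#'   validation block (default 5; training uses the final split).
#' @return List with `model` (trained forecaster) and `report`
#'   ([walk_forward_evaluate()] result).
#' @export
run_pipeline <- function(record, config = "C-01", win = window_spec(),
                         mspec = model_spec(), tspec = training_spec(),
                         carb_params = carb_kinetics_params(),
                         insulin_params = insulin_kinetics_params(),
                         k_splits = 5) {
  if (is.character(config)) config <- feature_config(config)
  needs_prep <- inherits(record$train_cgm, "irregular_series") ||
    anyNA(record$train_cgm$values) ||
    inherits(record$test_cgm, "irregular_series") ||
    anyNA(record$test_cgm$values)
  if (needs_prep) record <- suppressMessages(preprocess_record(record))
  mspec$horizon_len <- win$horizon_len

  train <- assemble_feature_matrix(record, config, "train",
                                   carb_params, insulin_params)
  test <- assemble_feature_matrix(record, config, "test",
                                  carb_params, insulin_params)
  plan <- rolling_origin_splits(nrow(train$matrix), k_splits)
  idx <- split_indices(plan, plan$k)
  st <- fit_standardizer(train$matrix[idx$train, , drop = FALSE])

  subset_series <- function(s, rows) {
    sampled_series(grid_spec(grid_times(s$grid)[rows[1]], length(rows),
                             s$grid$interval_mins),
                   s$values[rows], s$provenance[rows])
  }
  wtr <- make_windows(apply_standardizer(st, train$matrix[idx$train, , drop = FALSE]),
                      scale_target(st, train$target, idx$train, subset_series),
                      win)
  wva <- make_windows(apply_standardizer(st, train$matrix[idx$val, , drop = FALSE]),
                      scale_target(st, train$target, idx$val, subset_series),
                      win)
  model <- build_forecaster(mspec, n_channels = ncol(train$matrix))
  model <- train_forecaster(model, wtr$inputs, wtr$outputs, tspec,
                            val_inputs = wva$inputs,
                            val_outputs = wva$outputs,
                            standardizer = st)
  report <- walk_forward_evaluate(model, test$matrix, test$target, win,
                                  patient_id = record$patient_id,
                                  config_name = config$name)
  list(model = model, report = report)
}

# Standardize the target channel of a sampled_series subset, keeping
# provenance for masking.
scale_target <- function(st, target, rows, subset_series) {
  s <- subset_series(target, rows)
  sampled_series(s$grid, (s$values - st$mean[1]) / st$sd[1], s$provenance)
}

#' Compare input feature configurations
#'
#' Trains and evaluates every (configuration, horizon, seed) cell and
#' reports per-cell RMSE plus the seed-median summary grid — the
#' multivariate-vs-univariate comparison at the heart of the feature
#' transformation study.
#'
#' @param record A [patient_record()].
#' @param configs Character vector of configuration names.
#' @param horizons_mins Prediction horizons in minutes (30 and/or 60).
#' @param mspec A [model_spec()].
#' @param tspec A [training_spec()] (its seed is replaced per cell).
#' @param seeds Integer vector of training seeds.
#' @param history_len Input window length (default 6).
#' @param ... Passed to [run_pipeline()].
#' @return An object of class `config_comparison`: data.frame `runs`
#'   (one row per cell) and `summary` (seed-median RMSE per
#'   config x horizon).
#' @export
compare_configurations <- function(record, configs = c("C-01", "C-02", "C-03"),
                                   horizons_mins = c(30, 60),
                                   mspec = model_spec(),
                                   tspec = training_spec(),
                                   seeds = 1:5, history_len = 6, ...) {
  runs <- NULL
  for (ph in horizons_mins) {
    win <- window_spec(history_len = history_len, horizon_len = ph / 5)
    for (cf in configs) {
      for (sd_ in seeds) {
        tsp <- tspec
        tsp$seed <- as.integer(sd_)
        res <- run_pipeline(record, cf, win, mspec, tsp, ...)
        runs <- rbind(runs, data.frame(
          patient = res$report$patient_id, config = cf, horizon_mins = ph,
          seed = sd_, rmse = res$report$rmse,
          n_evaluated = res$report$n_evaluated))
      }
    }
  }
  summary <- stats::aggregate(rmse ~ config + horizon_mins, data = runs,
                              FUN = stats::median)
  names(summary)[names(summary) == "rmse"] <- "median_rmse"
  structure(list(runs = runs, summary = summary),
            class = "config_comparison")
}

#' @export
print.config_comparison <- function(x, ...) {
  cat("Seed-median walk-forward RMSE (mg/dL):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a configuration comparison to CSV
#' @param x A [compare_configurations()] result.
#' @param path Output CSV path (one row per patient/config/horizon/seed).
#' @return Invisibly, `path`.
#' @export
write_comparison_csv <- function(x, path) {
  stopifnot(inherits(x, "config_comparison"))
  utils::write.csv(x$runs, path, row.names = FALSE)
  invisible(path)
}
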