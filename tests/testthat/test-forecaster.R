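# The recurrent engine is hand-written, so its backward pass is checked
# against central finite differences — the canonical oracle for
# backpropagation.

numeric_grad_check <- function(spec, n_channels, seed = 42, tol = 1e-6) {
  arch <- glucast:::nn_arch(spec, n_channels)
  withr::with_seed(seed, {
    params <- glucast:::init_model_params(arch)
    X <- array(rnorm(3 * 4 * n_channels), dim = c(3, 4, n_channels))
    Tgt <- matrix(rnorm(3 * spec$horizon_len), 3, spec$horizon_len)
  })
  analytic <- glucast:::nn_loss_grads(params, arch, X, Tgt)$grads
  flat <- flatten_params(params)
  ga <- flatten_params(analytic)
  eps <- 1e-5
  gn <- vapply(seq_along(flat), function(i) {
    up <- flat; up[i] <- up[i] + eps
    dn <- flat; dn[i] <- dn[i] - eps
    lu <- glucast:::nn_loss_grads(set_flat_params(params, up), arch, X, Tgt)$loss
    ld <- glucast:::nn_loss_grads(set_flat_params(params, dn), arch, X, Tgt)$loss
    (lu - ld) / (2 * eps)
  }, numeric(1))
  max(abs(gn - ga)) / max(1, max(abs(ga)))
}

test_that("analytic gradients match finite differences (stacked LSTM)", {
  spec <- model_spec(layer1_units = 4, layer2_units = 3, horizon_len = 2,
                     dropout_rate = 0)
  expect_lt(numeric_grad_check(spec, n_channels = 2), 1e-6)
})

test_that("analytic gradients match finite differences (vanilla and bidirectional)", {
  vanilla <- model_spec(layer1_units = 5, stacked = FALSE, horizon_len = 3,
                        dropout_rate = 0)
  expect_lt(numeric_grad_check(vanilla, n_channels = 1), 1e-6)
  bidir <- model_spec(layer1_units = 3, layer2_units = 2,
                      bidirectional = TRUE, horizon_len = 2, dropout_rate = 0)
  expect_lt(numeric_grad_check(bidir, n_channels = 2), 1e-6)
})

test_that("parameter count tracks units, channels and horizon exactly", {
  lstm_n <- function(d, h) 4 * (d * h + h * h + h)
  n_params <- function(units1, units2, ch, hor) {
    forecaster_n_params(build_forecaster(
      model_spec(layer1_units = units1, layer2_units = units2,
                 horizon_len = hor), n_channels = ch))
  }
  expect_equal(n_params(8, 4, 1, 6),
               lstm_n(1, 8) + lstm_n(8, 4) + 4 * 6 + 6)
  expect_equal(n_params(8, 4, 3, 12),
               lstm_n(3, 8) + lstm_n(8, 4) + 4 * 12 + 12)
  # changing any of units / channels / horizon changes the count
  base <- n_params(8, 4, 1, 6)
  expect_false(n_params(9, 4, 1, 6) == base)
  expect_false(n_params(8, 5, 1, 6) == base)
  expect_false(n_params(8, 4, 2, 6) == base)
  expect_false(n_params(8, 4, 1, 12) == base)
})

test_that("the vanilla variant has exactly one recurrent layer", {
  stacked <- build_forecaster(model_spec(layer1_units = 4, layer2_units = 2), 1)
  vanilla <- build_forecaster(model_spec(layer1_units = 4, stacked = FALSE), 1)
  expect_equal(forecaster_n_recurrent_layers(stacked), 2)
  expect_equal(forecaster_n_recurrent_layers(vanilla), 1)
  expect_null(vanilla$params$l2f)
})

test_that("default spec accepts [?, 6, 1] inputs and emits 6 outputs; 12/2 likewise", {
  m30 <- build_forecaster(model_spec(layer1_units = 6, layer2_units = 4,
                                     horizon_len = 6), n_channels = 1)
  m30$trained <- TRUE
  out <- predict_horizon(m30, matrix(rnorm(6), 6, 1))
  expect_length(out, 6)
  expect_true(all(is.finite(out)))

  m60 <- build_forecaster(model_spec(layer1_units = 6, layer2_units = 4,
                                     horizon_len = 12), n_channels = 2)
  m60$trained <- TRUE
  expect_length(predict_horizon(m60, matrix(rnorm(12 * 2), 12, 2)), 12)
  expect_error(predict_horizon(m60, matrix(rnorm(12), 12, 1)), "channel")
})

test_that("six recent CGM values map to six predicted values", {
  m <- build_forecaster(model_spec(layer1_units = 4, layer2_units = 3,
                                   horizon_len = 6), 1)
  m$trained <- TRUE
  m$standardizer <- fit_standardizer(cbind(c(100, 150, 200, 120, 180, 90)))
  preds <- predict_horizon(m, cbind(c(152, 155, 156, 158, 161, 164)))
  expect_length(preds, 6)
  expect_true(all(is.finite(preds)))
})

test_that("training is reproducible for a fixed seed", {
  withr::with_seed(9, {
    X <- array(rnorm(40 * 6), dim = c(40, 6, 1))
    Y <- matrix(rnorm(40 * 6), 40, 6)
  })
  ts <- training_spec(max_epochs = 2, batch_size = 16, seed = 5)
  m <- build_forecaster(model_spec(layer1_units = 6, layer2_units = 4), 1)
  r1 <- train_forecaster(m, X, Y, ts)
  r2 <- train_forecaster(m, X, Y, ts)
  expect_identical(r1$history$train_loss[1], r2$history$train_loss[1])
  expect_identical(r1$params, r2$params)
  r3 <- train_forecaster(m, X, Y, training_spec(max_epochs = 2,
                                                batch_size = 16, seed = 6))
  expect_false(identical(r1$history$train_loss[1], r3$history$train_loss[1]))
})

test_that("a constant target is fit to near-zero, non-increasing loss", {
  X <- array(0, dim = c(30, 6, 1))
  Y <- matrix(0.5, 30, 6)
  m <- build_forecaster(model_spec(layer1_units = 4, layer2_units = 3,
                                   dropout_rate = 0), 1)
  fit <- train_forecaster(m, X, Y, training_spec(max_epochs = 150,
                                                 batch_size = 30,
                                                 learning_rate = 0.005,
                                                 early_stop_patience = 150,
                                                 seed = 2))
  expect_lt(tail(fit$history$train_loss, 1), 1e-4)
  # non-increasing up to numerical tolerance
  expect_true(all(diff(fit$history$train_loss) <= 1e-6))
  expect_equal(predict_horizon(fit, matrix(0, 6, 1)), rep(0.5, 6),
               tolerance = 0.05)
})

test_that("a noiseless sinusoid is learned below its own variability", {
  n <- 400
  x <- sin(seq_len(n) / 8)
  w <- make_windows(matrix(x, ncol = 1), x, window_spec(), drop_partial = TRUE)
  m <- build_forecaster(model_spec(layer1_units = 12, layer2_units = 6,
                                   dropout_rate = 0), 1)
  fit <- train_forecaster(m, w$inputs, w$outputs,
                          training_spec(max_epochs = 150, batch_size = 32,
                                        learning_rate = 0.01,
                                        early_stop_patience = 150, seed = 3))
  preds <- predict_horizon(fit, w$inputs)
  expect_lt(rmse_masked(preds, w$outputs), sd(x))
})

test_that("training drops masked-target examples and rejects shape mismatches", {
  withr::with_seed(1, {
    X <- array(rnorm(10 * 6), dim = c(10, 6, 1))
    Y <- matrix(rnorm(10 * 6), 10, 6)
  })
  Y[3, 2] <- NA
  m <- build_forecaster(model_spec(layer1_units = 3, layer2_units = 2), 1)
  expect_message(train_forecaster(m, X, Y,
                                  training_spec(max_epochs = 1, seed = 1)),
                 "dropping 1")
  expect_error(train_forecaster(m, X, Y[1:9, ],
                                training_spec(max_epochs = 1)), "disagree")
  expect_error(train_forecaster(m, X, Y[, 1:5],
                                training_spec(max_epochs = 1)), "horizon_len")
})

test_that("checkpoints round-trip weights, standardizer and predictions", {
  withr::with_seed(4, {
    X <- array(rnorm(20 * 6 * 2), dim = c(20, 6, 2))
    Y <- matrix(rnorm(20 * 6), 20, 6)
    st <- fit_standardizer(cbind(rnorm(50, 120, 25), rnorm(50, 10, 4)))
  })
  m <- build_forecaster(model_spec(layer1_units = 5, layer2_units = 3), 2)
  fit <- train_forecaster(m, X, Y, training_spec(max_epochs = 2, seed = 8),
                          standardizer = st)
  path <- withr::local_tempfile(fileext = ".json")
  save_forecaster(fit, path)
  back <- load_forecaster(path)
  w <- matrix(rnorm(12, 120, 20), 6, 2)
  expect_equal(predict_horizon(back, w), predict_horizon(fit, w),
               tolerance = 1e-12)
  expect_equal(back$training_spec$seed, 8L)
})
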