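# User-facing forecaster: specs, construction, training and prediction.

#' Forecaster architecture specification
#'
#' Stacked recurrent architecture: LSTM layer 1 (sequence-emitting) ->
#' leaky ReLU -> dropout -> LSTM layer 2 -> dropout -> dense head of
#' `horizon_len` linear units. With `stacked = FALSE` a single-layer
#' ("vanilla") LSTM is built. `bidirectional = TRUE` runs each
#' recurrent layer in both time directions and concatenates; it is off
#' by default — bidirectional recurrence is nonstandard for forecasting
#' (the future is not available at prediction time within a window) and
#' the default stacked model is the reference architecture.
#'
#' @param layer1_units Hidden units in LSTM layer 1 (default 128).
#' @param layer2_units Hidden units in LSTM layer 2 (default 64).
#' @param stacked Use the two-layer stack (default `TRUE`).
#' @param bidirectional Run layers in both directions (default `FALSE`).
#' @param leaky_relu_slope Negative-side slope (default 0.01).
#' @param dropout_rate Dropout probability during training (default 0.2).
#' @param horizon_len Output units: 6 for a 30-min horizon, 12 for
#'   60 min.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(layer1_units = 128, layer2_units = 64, stacked = TRUE,
                       bidirectional = FALSE, leaky_relu_slope = 0.01,
                       dropout_rate = 0.2, horizon_len = 6) {
  layer1_units <- as.integer(layer1_units)
  layer2_units <- as.integer(layer2_units)
  horizon_len <- as.integer(horizon_len)
  if (layer1_units < 1L || layer2_units < 1L) {
    stop("layer units must be positive", call. = FALSE)
  }
  if (horizon_len < 1L) stop("horizon_len must be positive", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(list(layer1_units = layer1_units, layer2_units = layer2_units,
                 stacked = isTRUE(stacked),
                 bidirectional = isTRUE(bidirectional),
                 leaky_relu_slope = leaky_relu_slope,
                 dropout_rate = dropout_rate, horizon_len = horizon_len),
            class = "model_spec")
}

#' Training specification
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Minibatch size (default 128).
#' @param max_epochs Epoch budget (default 100).
#' @param early_stop_patience Epochs without validation improvement
#'   before stopping (default 10).
#' @param seed Integer seed controlling weight initialization, batch
#'   shuffling and dropout masks; a fixed seed makes training fully
#'   reproducible.
#' @return An object of class `training_spec`.
#' @export
training_spec <- function(learning_rate = 0.001, batch_size = 128,
                          max_epochs = 100, early_stop_patience = 10,
                          seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "training_spec")
}

#' Build an untrained forecaster
#'
#' @param spec A [model_spec()].
#' @param n_channels Number of input channels (1 for C-01, 2 for C-02,
#'   3 for C-03).
#' @param init_seed Seed for the initial weights (retrained weights are
#'   re-initialized from the training seed).
#' @return An object of class `forecaster`.
#' @export
build_forecaster <- function(spec = model_spec(), n_channels = 1,
                             init_seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), n_channels >= 1)
  arch <- nn_arch(spec, as.integer(n_channels))
  params <- withr::with_seed(init_seed, init_model_params(arch))
  structure(list(spec = spec, n_channels = as.integer(n_channels),
                 arch = arch, params = params, trained = FALSE),
            class = "forecaster")
}

#' Number of trainable parameters
#' @param model A [build_forecaster()] object.
#' @return Integer parameter count.
#' @export
forecaster_n_params <- function(model) {
  stopifnot(inherits(model, "forecaster"))
  param_count(model$params)
}

#' Number of recurrent layers in the architecture
#' @param model A [build_forecaster()] object.
#' @return 1 for the vanilla variant, 2 for the stacked model.
#' @export
forecaster_n_recurrent_layers <- function(model) {
  if (model$arch$stacked) 2L else 1L
}

#' Train the forecaster
#'
#' Minimizes mean-squared error on the horizon vector with Adam,
#' recording per-epoch training (and validation) loss. Weights are
#' (re-)initialized from `training_spec$seed`, so the same seed yields
#' identical weights and losses. Examples whose target vector contains
#' non-finite values (masked / out-of-range targets) are dropped from
#' training. Early stopping restores the best validation weights.
#'
#' @param model A [build_forecaster()] object.
#' @param inputs Array `[examples, history_len, channels]`
#'   (standardized).
#' @param outputs Matrix `[examples, horizon_len]` (standardized).
#' @param spec A [training_spec()].
#' @param val_inputs,val_outputs Optional validation arrays of the same
#'   shapes.
#' @param standardizer Optional [fit_standardizer()] state attached for
#'   [predict_horizon()] to map raw windows in and mg/dL out.
#' @param verbose Print per-epoch losses.
#' @return A trained `forecaster` with a `history` data.frame.
#' @export
train_forecaster <- function(model, inputs, outputs, spec = training_spec(),
                             val_inputs = NULL, val_outputs = NULL,
                             standardizer = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "forecaster"), inherits(spec, "training_spec"))
  inputs <- as_window_array(inputs, model$n_channels)
  outputs <- as.matrix(outputs)
  if (dim(inputs)[1] != nrow(outputs)) {
    stop("inputs and outputs disagree on the number of examples",
         call. = FALSE)
  }
  if (ncol(outputs) != model$spec$horizon_len) {
    stop("outputs must have horizon_len = ", model$spec$horizon_len,
         " columns", call. = FALSE)
  }
  keep <- apply(outputs, 1, function(r) all(is.finite(r)))
  if (!all(keep)) {
    message(sprintf("train_forecaster: dropping %d example(s) with masked ",
                    sum(!keep)), "or out-of-range targets")
    inputs <- inputs[keep, , , drop = FALSE]
    outputs <- outputs[keep, , drop = FALSE]
  }
  n <- nrow(outputs)
  if (n == 0L) stop("no trainable examples", call. = FALSE)
  arch <- model$arch
  p_drop <- model$spec$dropout_rate
  f1 <- arch$dirs * arch$h1
  has_val <- !is.null(val_inputs) && !is.null(val_outputs)
  if (has_val) {
    val_inputs <- as_window_array(val_inputs, model$n_channels)
    val_outputs <- as.matrix(val_outputs)
    vkeep <- apply(val_outputs, 1, function(r) all(is.finite(r)))
    val_inputs <- val_inputs[vkeep, , , drop = FALSE]
    val_outputs <- val_outputs[vkeep, , drop = FALSE]
    has_val <- nrow(val_outputs) > 0L
  }

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = NULL, epoch = 0L)
  withr::with_seed(spec$seed, {
    params <- init_model_params(arch)
    opt <- adam_init(params)
    patience_left <- spec$early_stop_patience
    for (epoch in seq_len(spec$max_epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = spec$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        rows <- perm[s:min(s + spec$batch_size - 1L, n)]
        Xb <- inputs[rows, , , drop = FALSE]
        Yb <- outputs[rows, , drop = FALSE]
        B <- length(rows)
        masks <- NULL
        if (p_drop > 0) {
          masks <- list(
            d1 = array(rbinom(B * dim(Xb)[2] * f1, 1, 1 - p_drop) / (1 - p_drop),
                       dim = c(B, dim(Xb)[2], f1)),
            d2 = matrix(rbinom(B * arch$dense_in, 1, 1 - p_drop) / (1 - p_drop),
                        B, arch$dense_in))
        }
        lg <- nn_loss_grads(params, arch, Xb, Yb, masks)
        if (!is.finite(lg$loss)) {
          stop("training loss became non-finite at epoch ", epoch,
               "; reduce the learning rate or standardize the inputs",
               call. = FALSE)
        }
        step <- adam_step(params, lg$grads, opt, spec$learning_rate)
        params <- step$params
        opt <- step$state
        epoch_loss <- epoch_loss + lg$loss * B
      }
      train_loss <- epoch_loss / n
      monitor <- train_loss
      val_loss <- NA_real_
      if (has_val) {
        vf <- nn_forward(params, arch, val_inputs, NULL)
        val_loss <- mean((vf$Y - val_outputs)^2)
        monitor <- val_loss
      }
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = train_loss,
                                           val_loss = val_loss))
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %s", epoch, train_loss,
                        ifelse(is.na(val_loss), "-", sprintf("%.5f", val_loss))))
      }
      if (monitor < best$loss - 1e-12) {
        best <- list(loss = monitor, params = params, epoch = epoch)
        patience_left <- spec$early_stop_patience
      } else {
        patience_left <- patience_left - 1L
        if (patience_left <= 0L) break
      }
    }
  })
  model$params <- best$params
  model$trained <- TRUE
  model$history <- history
  model$best_epoch <- best$epoch
  model$training_spec <- spec
  model$standardizer <- standardizer
  model
}

#' Predict a multi-step horizon in mg/dL
#'
#' Applies the trained network to one or more history windows. When a
#' standardizer is attached (the usual case), raw mg/dL-scale windows
#' are standardized on the way in and predictions inverse-transformed
#' back to mg/dL on the way out; without one, values pass through on
#' the model scale.
#'
#' @param model A trained `forecaster`.
#' @param window Numeric `[history_len, channels]` matrix (or vector for
#'   one channel), or a batch array `[examples, history_len, channels]`.
#' @return Numeric vector of `horizon_len` predictions (or a matrix for
#'   a batch).
#' @export
predict_horizon <- function(model, window) {
  stopifnot(inherits(model, "forecaster"))
  if (!isTRUE(model$trained)) {
    warning("forecaster has not been trained; predictions use initial weights",
            call. = FALSE)
  }
  single <- !(is.array(window) && length(dim(window)) == 3L)
  X <- as_window_array(window, model$n_channels)
  if (!is.null(model$standardizer)) {
    X <- apply_standardizer(model$standardizer, X)
  }
  fwd <- nn_forward(model$params, model$arch, X, NULL)
  Y <- fwd$Y
  if (!is.null(model$standardizer)) {
    Y <- invert_standardizer(model$standardizer, Y, channel = 1)
  }
  if (single) as.numeric(Y[1, ]) else Y
}

# Coerce a window (vector [T], matrix [T, C] or array [B, T, C]) to a
# [B, T, C] array and check the channel count.
as_window_array <- function(x, n_channels) {
  if (is.array(x) && length(dim(x)) == 3L) {
    arr <- x
  } else {
    if (is.null(dim(x))) x <- cbind(x)
    arr <- array(x, dim = c(1L, nrow(x), ncol(x)))
    arr[1, , ] <- x
  }
  if (dim(arr)[3] != n_channels) {
    stop(sprintf("window has %d channel(s); the model expects %d",
                 dim(arr)[3], n_channels), call. = FALSE)
  }
  arr
}
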