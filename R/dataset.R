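# Feature matrix assembly, sliding-window example construction,
# rolling-origin cross-validation splits, and standardization.

#' Input feature configuration
#'
#' The three channel sets compared in the study: `C-01` is univariate
#' CGM; `C-02` adds operative carbs; `C-03` adds active insulin.
#'
#' @param name `"C-01"`, `"C-02"` or `"C-03"`.
#' @return An object of class `feature_config` with a `channels` field.
#' @export
feature_config <- function(name = c("C-01", "C-02", "C-03")) {
  name <- match.arg(name)
  channels <- switch(name,
    "C-01" = "cgm",
    "C-02" = c("cgm", "operative_carbs"),
    "C-03" = c("cgm", "operative_carbs", "active_insulin"))
  structure(list(name = name, channels = channels), class = "feature_config")
}

#' Windowing geometry
#'
#' `history_len` input samples predict the next `horizon_len` samples
#' (6 samples = 30 min, 12 = 60 min at 5-min sampling). Window offsets
#' advance by `stride`; the default `stride = history_len` tiles the
#' series into non-overlapping input windows, matching the worked
#' example counts (9288 samples / 6 = 1548 training examples).
#'
#' @param history_len Input window length in samples (default 6).
#' @param horizon_len Prediction horizon in samples (6 or 12).
#' @param stride Offset between consecutive windows (default
#'   `history_len`).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(history_len = 6, horizon_len = 6,
                        stride = history_len) {
  history_len <- as.integer(history_len)
  horizon_len <- as.integer(horizon_len)
  stride <- as.integer(stride)
  if (any(c(history_len, horizon_len, stride) < 1L)) {
    stop("window lengths and stride must be positive", call. = FALSE)
  }
  structure(list(history_len = history_len, horizon_len = horizon_len,
                 stride = stride), class = "window_spec")
}

#' Prediction horizon in minutes for a window spec
#' @param spec A [window_spec()].
#' @param interval_mins Sampling interval (default 5).
#' @return Horizon in minutes.
#' @export
horizon_minutes <- function(spec, interval_mins = 5) {
  spec$horizon_len * interval_mins
}

#' Assemble the multivariate feature matrix for one record segment
#'
#' Computes the configured channels on the CGM grid, in the
#' configuration's order: the CGM itself, the operative-carbs transform
#' of the meal log, and the active-insulin transform of the bolus log.
#' The target is the CGM series with its provenance preserved so imputed
#' samples can be masked at evaluation.
#'
#' @param record A preprocessed [patient_record()] (regular, imputed
#'   CGM).
#' @param config A [feature_config()] or its name.
#' @param role Which segment: `"train"` or `"test"`.
#' @param carb_params A [carb_kinetics_params()].
#' @param insulin_params An [insulin_kinetics_params()].
#' @return List with `matrix` (samples x channels, named columns) and
#'   `target` (the CGM [sampled_series()]).
#' @export
assemble_feature_matrix <- function(record, config, role = c("train", "test"),
                                    carb_params = carb_kinetics_params(),
                                    insulin_params = insulin_kinetics_params()) {
  role <- match.arg(role)
  if (is.character(config)) config <- feature_config(config)
  stopifnot(inherits(record, "patient_record"),
            inherits(config, "feature_config"))
  cgm <- if (role == "train") record$train_cgm else record$test_cgm
  if (!inherits(cgm, "sampled_series")) {
    stop("record must be preprocessed first (see preprocess_record())",
         call. = FALSE)
  }
  if (anyNA(cgm$values)) {
    stop("CGM series still has undefined samples; run impute_series()",
         call. = FALSE)
  }
  cols <- lapply(config$channels, function(ch) {
    switch(ch,
      cgm = cgm$values,
      operative_carbs = {
        if (length(record$meals$times) == 0L && config$name != "C-01") {
          # an empty log is legitimate; the channel is identically zero
        }
        operative_carbs_series(record$meals, cgm$grid, carb_params)$values
      },
      active_insulin =
        active_insulin_series(record$boluses, cgm$grid, insulin_params)$values,
      stop("unknown channel: ", ch, call. = FALSE))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- config$channels
  list(matrix = m, target = cgm)
}

#' Build windowed sequence-to-sequence examples
#'
#' Slices the feature matrix into examples at offsets `0, stride,
#' 2*stride, ...`: each example pairs `history_len` input rows with the
#' following `horizon_len` target values. The target mask marks which
#' target positions are sensor-recorded (`observed` provenance) and
#' in-range; imputed or out-of-range targets are masked (and the
#' out-of-range ones set to `NA`). With `drop_partial = TRUE`, windows
#' whose targets are not fully in-range are dropped instead.
#'
#' @param matrix Numeric matrix, samples x channels.
#' @param target A [sampled_series()] (or numeric vector) of targets.
#' @param spec A [window_spec()].
#' @param drop_partial Drop windows with incomplete targets
#'   (default `FALSE`, which keeps every full-history window and masks
#'   the missing targets).
#' @return List with `inputs` (examples x history_len x channels),
#'   `outputs` (examples x horizon_len), `mask` (logical, TRUE =
#'   evaluable) and `offsets` (0-based window offsets).
#' @export
make_windows <- function(matrix, target, spec = window_spec(),
                         drop_partial = FALSE) {
  stopifnot(inherits(spec, "window_spec"))
  if (is.null(dim(matrix))) matrix <- cbind(matrix)
  n <- nrow(matrix)
  h <- spec$history_len; ph <- spec$horizon_len
  if (inherits(target, "sampled_series")) {
    tvals <- target$values
    tobs <- target$provenance == "observed"
  } else {
    tvals <- as.numeric(target)
    tobs <- rep(TRUE, length(tvals))
  }
  stopifnot(length(tvals) == n)
  min_n <- if (drop_partial) h + ph else h
  if (n < min_n) {
    stop(sprintf("series too short for windowing: need >= %d rows, have %d",
                 min_n, n), call. = FALSE)
  }
  max_offset <- if (drop_partial) n - h - ph else n - h
  offsets <- seq(0L, max_offset, by = spec$stride)
  ne <- length(offsets)
  inputs <- array(NA_real_, dim = c(ne, h, ncol(matrix)),
                  dimnames = list(NULL, NULL, colnames(matrix)))
  outputs <- base::matrix(NA_real_, ne, ph)
  mask <- base::matrix(FALSE, ne, ph)
  for (e in seq_len(ne)) {
    o <- offsets[e]
    inputs[e, , ] <- matrix[(o + 1L):(o + h), , drop = FALSE]
    tidx <- (o + h + 1L):(o + h + ph)
    inb <- tidx <= n
    outputs[e, inb] <- tvals[tidx[inb]]
    mask[e, inb] <- tobs[tidx[inb]]
  }
  list(inputs = inputs, outputs = outputs, mask = mask, offsets = offsets)
}

#' Rolling-origin cross-validation plan
#'
#' Time-ordered splits where each successive training set is a superset
#' of the previous and a constant-size validation block immediately
#' follows it: `val_size = floor(n/(k+1))` and the i-th training size is
#' `n - (k - i + 1) * val_size` (i = 1..k). For n = 11,611 and k = 5
#' this gives training sizes 1936, 3871, 5806, 7741, 9676 with 1935
#' validation samples each.
#'
#' @param n_total Total samples.
#' @param k Number of splits (default 5, >= 2).
#' @return An object of class `split_plan` with `val_size` and
#'   `train_sizes`.
#' @export
rolling_origin_splits <- function(n_total, k = 5) {
  n_total <- as.integer(n_total); k <- as.integer(k)
  if (k < 2L) stop("need k >= 2 splits", call. = FALSE)
  if (n_total < k + 1L) {
    stop("n_total too small: need at least k + 1 samples", call. = FALSE)
  }
  val_size <- n_total %/% (k + 1L)
  train_sizes <- n_total - (k:1) * val_size
  structure(list(n_total = n_total, k = k, val_size = val_size,
                 train_sizes = train_sizes), class = "split_plan")
}

#' Row indices of one rolling-origin split
#'
#' @param plan A [rolling_origin_splits()] plan.
#' @param i Split number in `1..k`.
#' @return List with integer vectors `train` and `val`; the validation
#'   block immediately follows the training block.
#' @export
split_indices <- function(plan, i) {
  stopifnot(inherits(plan, "split_plan"), i >= 1, i <= plan$k)
  tr <- plan$train_sizes[i]
  list(train = seq_len(tr), val = (tr + 1L):(tr + plan$val_size))
}

#' Fit a per-channel standardizer on training rows
#'
#' @param x Numeric matrix (training rows only; fitting on validation or
#'   test rows would leak information).
#' @return An object of class `standardizer` with per-channel `mean` and
#'   `sd`.
#' @export
fit_standardizer <- function(x) {
  if (is.null(dim(x))) x <- cbind(x)
  mu <- colMeans(x)
  sigma <- apply(x, 2, stats::sd)
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("zero-variance channel(s): ",
         paste(which(!(sigma > 0)), collapse = ", "),
         "; constant channels cannot be standardized", call. = FALSE)
  }
  structure(list(mean = mu, sd = sigma), class = "standardizer")
}

#' Apply a standardizer
#' @param state A [fit_standardizer()] result.
#' @param x Matrix (or 3-d window array) with matching channels in the
#'   last dimension.
#' @return `(x - mean) / sd` per channel, same shape.
#' @export
apply_standardizer <- function(state, x) {
  stopifnot(inherits(state, "standardizer"))
  scale_channel <- function(v, ch) (v - state$mean[ch]) / state$sd[ch]
  transform_channels(x, length(state$mean), scale_channel)
}

#' Invert a standardizer
#' @param state A [fit_standardizer()] result.
#' @param y Standardized values (vector/matrix) of a single channel, or
#'   a full matrix/array when `channel = NULL`.
#' @param channel Channel index for single-channel inversion (default 1,
#'   the CGM/target channel).
#' @return Values on the original scale.
#' @export
invert_standardizer <- function(state, y, channel = 1) {
  stopifnot(inherits(state, "standardizer"))
  if (is.null(channel)) {
    unscale <- function(v, ch) v * state$sd[ch] + state$mean[ch]
    return(transform_channels(y, length(state$mean), unscale))
  }
  y * state$sd[channel] + state$mean[channel]
}

transform_channels <- function(x, n_channels, f) {
  if (is.array(x) && length(dim(x)) == 3L) {
    stopifnot(dim(x)[3] == n_channels)
    for (ch in seq_len(n_channels)) x[, , ch] <- f(x[, , ch], ch)
    return(x)
  }
  if (is.null(dim(x))) x <- cbind(x)
  stopifnot(ncol(x) == n_channels)
  for (ch in seq_len(n_channels)) x[, ch] <- f(x[, ch], ch)
  x
}
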