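# Forecaster checkpointing: weights plus a reproducibility sidecar
# (architecture, standardizer, training seed) in plain JSON.

#' Save a trained forecaster
#'
#' Writes the weights and everything needed to reproduce or reuse the
#' model — architecture spec, channel count, standardizer, training
#' spec (including its seed) and loss history — as JSON at full double
#' precision.
#'
#' @param model A `forecaster`.
#' @param path Output `.json` path.
#' @return Invisibly, `path`.
#' @export
save_forecaster <- function(model, path) {
  stopifnot(inherits(model, "forecaster"))
  payload <- list(
    format = "glucast-forecaster-v1",
    spec = unclass(model$spec),
    n_channels = model$n_channels,
    trained = isTRUE(model$trained),
    training_spec = if (!is.null(model$training_spec)) unclass(model$training_spec),
    standardizer = if (!is.null(model$standardizer)) unclass(model$standardizer),
    history = model$history,
    params = model$params
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' Load a forecaster checkpoint
#'
#' @param path Path written by [save_forecaster()].
#' @return A `forecaster` whose predictions match the saved model.
#' @export
load_forecaster <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyMatrix = TRUE)
  if (!identical(payload$format, "glucast-forecaster-v1")) {
    stop("not a glucast forecaster checkpoint: ", path, call. = FALSE)
  }
  spec <- do.call(model_spec, payload$spec)
  model <- build_forecaster(spec, payload$n_channels)
  fix <- function(p) {
    list(W = as.matrix(p$W), U = as.matrix(p$U), b = as.numeric(p$b))
  }
  params <- payload$params
  for (nm in intersect(names(params), c("l1f", "l1b", "l2f", "l2b"))) {
    params[[nm]] <- fix(params[[nm]])
  }
  params$dense <- list(W = as.matrix(payload$params$dense$W),
                       b = as.numeric(payload$params$dense$b))
  model$params <- params[names(model$params)]
  model$trained <- isTRUE(payload$trained)
  if (!is.null(payload$standardizer)) {
    model$standardizer <- structure(
      list(mean = as.numeric(payload$standardizer$mean),
           sd = as.numeric(payload$standardizer$sd)),
      class = "standardizer")
  }
  if (!is.null(payload$training_spec)) {
    model$training_spec <- do.call(training_spec, payload$training_spec)
  }
  model$history <- payload$history
  model
}
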