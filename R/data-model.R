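# Core domain types: regular-grid series with provenance, irregular event
# logs, and the per-patient record that ties them together.

OHIO_TS_FORMAT <- "%d-%m-%Y %H:%M:%S"
PROVENANCE_LEVELS <- c("observed", "inserted_missing", "imputed", "smoothed")

#' Regular sampling grid
#'
#' Describes a half-open regular time grid `[start, start + n * interval)`:
#' sample `k` (0-based) sits at `start_time + k * interval`. CGM data uses
#' the 5-minute interval of the Medtronic sensor.
#'
#' @param start_time `POSIXct` timestamp of sample 0.
#' @param n_samples Number of samples (>= 0).
#' @param interval_mins Sampling interval in minutes (> 0, default 5).
#' @return An object of class `grid_spec`.
#' @seealso [grid_times()], [sampled_series()]
#' @export
grid_spec <- function(start_time, n_samples, interval_mins = 5) {
  start_time <- as_utc_time(start_time)
  stopifnot(length(start_time) == 1L, !is.na(start_time))
  if (!is.numeric(interval_mins) || interval_mins <= 0) {
    stop("`interval_mins` must be a positive number of minutes", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 0L) {
    stop("`n_samples` must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(start_time = start_time, n_samples = n_samples,
         interval_mins = as.numeric(interval_mins)),
    class = "grid_spec"
  )
}

#' Grid sample times
#'
#' @param grid A [grid_spec()].
#' @return `POSIXct` vector of length `grid$n_samples`.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  grid$start_time + seq_len(grid$n_samples) * 60 * grid$interval_mins -
    60 * grid$interval_mins
}

#' Regular-grid series with per-sample provenance
#'
#' A numeric series on a [grid_spec()] where every sample carries a
#' provenance flag: `observed` (sensor-recorded), `inserted_missing`
#' (grid slot with no observation; value is `NA`), `imputed`
#' (filled by [impute_series()] or [align_features()]) or `smoothed`
#' (altered by [median_smooth()]). A value may be `NA` only while its
#' provenance is `inserted_missing`.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric vector, length `grid$n_samples` (CGM in mg/dL).
#' @param provenance Character vector of per-sample flags; recycled if
#'   length 1. Defaults to `"observed"`.
#' @return An object of class `sampled_series`.
#' @export
sampled_series <- function(grid, values, provenance = "observed") {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.numeric(values)
  if (length(provenance) == 1L) provenance <- rep(provenance, length(values))
  if (length(values) != grid$n_samples || length(provenance) != grid$n_samples) {
    stop("`values` and `provenance` must have length `grid$n_samples`",
         call. = FALSE)
  }
  bad <- setdiff(unique(provenance), PROVENANCE_LEVELS)
  if (length(bad)) {
    stop("unknown provenance flag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  undefined <- !is.finite(values)
  if (any(undefined & provenance != "inserted_missing")) {
    stop("values may be undefined (NA) only where provenance is ",
         "'inserted_missing'", call. = FALSE)
  }
  structure(list(grid = grid, values = values, provenance = provenance),
            class = "sampled_series")
}

#' @export
length.sampled_series <- function(x) x$grid$n_samples

#' @export
print.sampled_series <- function(x, ...) {
  tab <- table(factor(x$provenance, levels = PROVENANCE_LEVELS))
  cat(sprintf("<sampled_series> %d samples @ %g min from %s\n",
              length(x), x$grid$interval_mins,
              format(x$grid$start_time, OHIO_TS_FORMAT)))
  cat("  provenance:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Irregular time-stamped point series
#'
#' Raw sensor observations before grid regularization (e.g. glucose events
#' straight from an Ohio XML file). Times must be strictly increasing.
#'
#' @param times `POSIXct` timestamps, strictly increasing.
#' @param values Numeric values, same length.
#' @return An object of class `irregular_series`.
#' @export
irregular_series <- function(times, values) {
  times <- as_utc_time(times)
  values <- as.numeric(values)
  stopifnot(length(times) == length(values))
  if (anyNA(times)) stop("irregular series times contain NA", call. = FALSE)
  if (length(times) > 1L && any(diff(as.numeric(times)) <= 0)) {
    stop("irregular series times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = times, values = values), class = "irregular_series")
}

#' Event log (meals or boluses)
#'
#' Irregular time-stamped events with positive magnitudes: grams of
#' carbohydrate for `kind = "meal"`, insulin units for `kind = "bolus"`.
#'
#' @param kind Either `"meal"` or `"bolus"`.
#' @param times `POSIXct` event timestamps, strictly increasing.
#' @param magnitudes Positive numeric magnitudes, same length as `times`.
#' @return An object of class `event_series`.
#' @export
event_series <- function(kind = c("meal", "bolus"), times = as.POSIXct(character(), tz = "UTC"),
                         magnitudes = numeric()) {
  kind <- match.arg(kind)
  times <- as_utc_time(times)
  magnitudes <- as.numeric(magnitudes)
  if (length(times) != length(magnitudes)) {
    stop("`times` and `magnitudes` must have equal length", call. = FALSE)
  }
  if (anyNA(times) || anyNA(magnitudes)) {
    stop("event series must not contain NA", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(as.numeric(times)) <= 0)) {
    stop("event times must be strictly increasing", call. = FALSE)
  }
  if (any(magnitudes <= 0)) {
    stop("event magnitudes must be positive", call. = FALSE)
  }
  structure(list(kind = kind, times = times, magnitudes = magnitudes),
            class = "event_series")
}

#' Per-patient record
#'
#' Bundles one patient's training and test CGM series (irregular as read,
#' or regular after preprocessing), meal and bolus event logs, and any
#' extra aligned series (heart rate etc., carried but unused by the
#' forecasting pipeline).
#'
#' @param patient_id Character id.
#' @param train_cgm,test_cgm [irregular_series()] or [sampled_series()].
#' @param meals,boluses [event_series()] of the matching kind.
#' @param extra_series Named list of additional series (optional).
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, train_cgm, test_cgm,
                           meals = event_series("meal"),
                           boluses = event_series("bolus"),
                           extra_series = list()) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  for (s in list(train_cgm, test_cgm)) {
    if (!inherits(s, c("irregular_series", "sampled_series"))) {
      stop("CGM series must be irregular_series or sampled_series",
           call. = FALSE)
    }
  }
  stopifnot(inherits(meals, "event_series"), meals$kind == "meal",
            inherits(boluses, "event_series"), boluses$kind == "bolus")
  structure(
    list(patient_id = patient_id, train_cgm = train_cgm, test_cgm = test_cgm,
         meals = meals, boluses = boluses, extra_series = extra_series),
    class = "patient_record"
  )
}

#' @export
print.patient_record <- function(x, ...) {
  n_of <- function(s) if (inherits(s, "sampled_series")) length(s) else length(s$times)
  cat(sprintf("<patient_record> id=%s: train %d, test %d CGM samples; %d meals, %d boluses\n",
              x$patient_id, n_of(x$train_cgm), n_of(x$test_cgm),
              length(x$meals$times), length(x$boluses$times)))
  invisible(x)
}

series_time_range <- function(s) {
  if (inherits(s, "sampled_series")) {
    if (length(s) == 0L) return(NULL)
    range(c(s$grid$start_time,
            s$grid$start_time + s$grid$n_samples * 60 * s$grid$interval_mins))
  } else {
    if (length(s$times) == 0L) return(NULL)
    range(s$times)
  }
}

#' Validate a patient record
#'
#' Checks record invariants and returns machine-readable findings rather
#' than raising: duplicate or non-increasing timestamps, non-positive
#' event magnitudes, train/test time overlap, and events outside the
#' record's time span. An empty character vector means the record is
#' well formed.
#'
#' @param record A [patient_record()].
#' @return Character vector of findings (empty if valid).
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "patient_record"))
  findings <- character()
  check_times <- function(times, label) {
    if (length(times) > 1L) {
      d <- diff(as.numeric(times))
      if (any(d == 0)) {
        findings <<- c(findings, sprintf(
          "%s: duplicate timestamps at positions %s", label,
          paste(which(d == 0), collapse = ", ")))
      }
      if (any(d < 0)) {
        findings <<- c(findings, sprintf(
          "%s: time inversions at positions %s", label,
          paste(which(d < 0), collapse = ", ")))
      }
    }
  }
  for (nm in c("meals", "boluses")) {
    ev <- record[[nm]]
    check_times(ev$times, nm)
    bad <- which(ev$magnitudes <= 0)
    for (i in bad) {
      findings <- c(findings, sprintf(
        "%s: non-positive magnitude %g at event %d (%s)", nm,
        ev$magnitudes[i], i, format(ev$times[i], OHIO_TS_FORMAT)))
    }
  }
  if (inherits(record$train_cgm, "irregular_series")) {
    check_times(record$train_cgm$times, "train_cgm")
  }
  if (inherits(record$test_cgm, "irregular_series")) {
    check_times(record$test_cgm$times, "test_cgm")
  }
  tr <- series_time_range(record$train_cgm)
  te <- series_time_range(record$test_cgm)
  if (!is.null(tr) && !is.null(te) && tr[1] < te[2] && te[1] < tr[2]) {
    findings <- c(findings, "train and test series overlap in time")
  }
  span <- range(c(tr, te))
  if (!is.null(span) && length(span) == 2L) {
    for (nm in c("meals", "boluses")) {
      ev <- record[[nm]]
      out <- which(ev$times < span[1] | ev$times > span[2])
      for (i in out) {
        findings <- c(findings, sprintf(
          "%s: event %d at %s falls outside the record time span", nm, i,
          format(ev$times[i], OHIO_TS_FORMAT)))
      }
    }
  }
  findings
}

# --- internal helpers -------------------------------------------------------

as_utc_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (is.character(x)) {
    out <- as.POSIXct(x, tz = "UTC")
    return(out)
  }
  as.POSIXct(x, tz = "UTC", origin = "1970-01-01")
}

parse_ohio_time <- function(x) {
  out <- as.POSIXct(strptime(x, OHIO_TS_FORMAT, tz = "UTC"))
  if (anyNA(out)) {
    stop("timestamp(s) not in 'DD-MM-YYYY HH:MM:SS' format: ",
         paste(utils::head(x[is.na(out)], 3), collapse = "; "), call. = FALSE)
  }
  out
}

format_ohio_time <- function(x) format(x, OHIO_TS_FORMAT, tz = "UTC")
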