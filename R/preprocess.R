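# CGM preprocessing: grid regularization, gap imputation, median
# smoothing, and alignment of auxiliary series onto the CGM grid.

#' Regularize an irregular CGM series onto a fixed grid
#'
#' Anchors a regular grid at the first observation and maps every
#' observed point to its nearest grid slot (tolerance half an interval
#' by construction of rounding). Slots with no observation are flagged
#' `inserted_missing` with an undefined (`NA`) value; observed values
#' are never altered.
#'
#' @param points An [irregular_series()], or anything with `$times` and
#'   `$values`.
#' @param interval_mins Grid interval in minutes (default 5).
#' @return A [sampled_series()] spanning first to last observation.
#' @export
regularize_grid <- function(points, interval_mins = 5) {
  times <- as_utc_time(points$times)
  values <- as.numeric(points$values)
  stopifnot(length(times) == length(values), interval_mins > 0)
  if (length(times) == 0L) {
    return(sampled_series(grid_spec(Sys.time(), 0L, interval_mins),
                          numeric(), character()))
  }
  if (length(times) > 1L && any(diff(as.numeric(times)) <= 0)) {
    stop("observation times must be strictly increasing", call. = FALSE)
  }
  offset_mins <- as.numeric(times - times[1], units = "mins")
  slot <- as.integer(round(offset_mins / interval_mins))
  dup <- which(duplicated(slot))
  if (length(dup)) {
    stop("observations collide on grid slot(s) ",
         paste(unique(slot[dup]), collapse = ", "),
         " (two points within half an interval)", call. = FALSE)
  }
  n <- slot[length(slot)] + 1L
  vals <- rep(NA_real_, n)
  prov <- rep("inserted_missing", n)
  vals[slot + 1L] <- values
  prov[slot + 1L] <- "observed"
  sampled_series(grid_spec(times[1], n, interval_mins), vals, prov)
}

#' Fill missing grid slots by forward fill (limit 1) or linear interpolation
#'
#' Runs of exactly one missing slot take the previous observed value
#' (forward fill with limit 1); runs of two or more take linear
#' interpolation between the bracketing observed values. Filled slots
#' are flagged `imputed`; observed slots are untouched. The series must
#' start and end with defined samples so every gap is bracketed.
#'
#' @param series A [sampled_series()] from [regularize_grid()].
#' @return A fully defined [sampled_series()].
#' @export
impute_series <- function(series) {
  stopifnot(inherits(series, "sampled_series"))
  vals <- series$values
  prov <- series$provenance
  miss <- prov == "inserted_missing"
  if (!any(miss)) return(series)
  n <- length(vals)
  if (miss[1] || miss[n]) {
    stop("series has a leading or trailing missing run with no bracketing ",
         "observation; truncate to the observed span first", call. = FALSE)
  }
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    lo <- starts[j] - 1L
    hi <- ends[j] + 1L
    run <- starts[j]:ends[j]
    if (r$lengths[j] == 1L) {
      vals[run] <- vals[lo]                       # forward fill, limit 1
    } else {
      w <- (run - lo) / (hi - lo)
      vals[run] <- vals[lo] + w * (vals[hi] - vals[lo])
    }
    prov[run] <- "imputed"
  }
  message(sprintf("impute_series: filled %d missing sample(s) in %d run(s)",
                  sum(miss), sum(r$values)))
  sampled_series(series$grid, vals, prov)
}

#' Median-smooth a fully defined series
#'
#' Replaces each value by the median of a centered window, shrinking the
#' window symmetrically near the edges. Samples whose value changed are
#' flagged `smoothed`. Intended for TRAINING data only: test data must
#' be left unsmoothed so evaluation compares against sensor readings.
#'
#' @param series A fully defined [sampled_series()] (post-imputation).
#' @param window Odd window length >= 3 (default 5, i.e. 25 min at 5-min
#'   sampling; wide enough to remove 1-2 sample sensor spikes without
#'   flattening meal rises).
#' @return A [sampled_series()].
#' @export
median_smooth <- function(series, window = 5) {
  stopifnot(inherits(series, "sampled_series"))
  window <- as.integer(window)
  if (is.na(window) || window < 3L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  if (anyNA(series$values)) {
    stop("median_smooth requires a fully defined series; run ",
         "impute_series() first", call. = FALSE)
  }
  x <- series$values
  n <- length(x)
  h <- window %/% 2L
  out <- x
  for (i in seq_len(n)) {
    hi <- min(h, i - 1L, n - i)
    out[i] <- stats::median(x[(i - hi):(i + hi)])
  }
  prov <- series$provenance
  changed <- out != x
  prov[changed] <- "smoothed"
  if (any(changed)) {
    message(sprintf("median_smooth: altered %d of %d sample(s)",
                    sum(changed), n))
  }
  sampled_series(series$grid, out, prov)
}

#' Align auxiliary series onto a reference grid
#'
#' Resamples each irregular series onto the reference CGM grid: each
#' observation maps to the nearest grid slot within half an interval;
#' interior gaps are then filled as in [impute_series()] and edge gaps
#' extended from the nearest observation, all flagged `imputed`.
#'
#' @param reference A regular [sampled_series()] (the CGM).
#' @param others Named list of [irregular_series()] (or `$times`/`$values`
#'   lists).
#' @return Named list of [sampled_series()] on the reference grid.
#' @export
align_features <- function(reference, others) {
  stopifnot(inherits(reference, "sampled_series"), is.list(others))
  grid <- reference$grid
  half <- grid$interval_mins / 2
  lapply(stats::setNames(others, names(others)), function(s) {
    times <- as_utc_time(s$times)
    vals <- rep(NA_real_, grid$n_samples)
    prov <- rep("inserted_missing", grid$n_samples)
    if (length(times) == 0L) {
      warning("empty feature series: output is all missing", call. = FALSE)
      return(sampled_series(grid, vals, prov))
    }
    off <- as.numeric(times - grid$start_time, units = "mins")
    slot <- round(off / grid$interval_mins)
    ok <- abs(off - slot * grid$interval_mins) <= half &
      slot >= 0 & slot < grid$n_samples
    vals[slot[ok] + 1L] <- as.numeric(s$values)[ok]
    prov[slot[ok] + 1L] <- "observed"
    defined <- which(!is.na(vals))
    if (length(defined) == 0L) {
      warning("no observations fall on the reference grid", call. = FALSE)
      return(sampled_series(grid, vals, prov))
    }
    first <- defined[1]; last <- defined[length(defined)]
    if (first > 1L) {
      vals[1:(first - 1L)] <- vals[first]
      prov[1:(first - 1L)] <- "imputed"
    }
    if (last < grid$n_samples) {
      vals[(last + 1L):grid$n_samples] <- vals[last]
      prov[(last + 1L):grid$n_samples] <- "imputed"
    }
    core <- sampled_series(grid, vals, prov)
    if (any(prov == "inserted_missing")) core <- suppressMessages(impute_series(core))
    core
  })
}

#' Preprocess a patient record end-to-end
#'
#' Regularizes and imputes both CGM series and median-smooths the
#' training series only (test data must remain as the sensor recorded
#' it; imputed test samples are masked at evaluation instead). Stage
#' counts are reported via messages.
#'
#' @param record A [patient_record()] with irregular CGM series.
#' @param interval_mins Grid interval in minutes (default 5).
#' @param smooth_window Median filter window (odd; default 5). Use
#'   `NULL` to skip smoothing.
#' @return The record with `train_cgm`/`test_cgm` as regular
#'   [sampled_series()].
#' @export
preprocess_record <- function(record, interval_mins = 5, smooth_window = 5) {
  stopifnot(inherits(record, "patient_record"))
  prep <- function(s, smooth) {
    if (inherits(s, "irregular_series")) s <- regularize_grid(s, interval_mins)
    n_inserted <- sum(s$provenance == "inserted_missing")
    message(sprintf("regularize: %d observed + %d inserted = %d samples",
                    sum(s$provenance == "observed"), n_inserted, length(s)))
    if (length(s) > 0L) s <- impute_series(s)
    if (smooth && !is.null(smooth_window) && length(s) > 0L) {
      s <- median_smooth(s, smooth_window)
    }
    s
  }
  record$train_cgm <- prep(record$train_cgm, smooth = TRUE)
  record$test_cgm <- prep(record$test_cgm, smooth = FALSE)
  record
}
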