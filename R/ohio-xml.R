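# Reader/writer for the Ohio T1DM XML dialect.
#
# Layout: <patient id="..."> containing container elements
# <glucose_level>, <meal>, <bolus>, each holding
# <event ts="DD-MM-YYYY HH:MM:SS" value=|carbs=|dose="..."/> children.
# Other containers (basal, finger_stick, exercise, ...) carry no pipeline
# semantics and are skipped with a warning.

OHIO_VALUE_ATTR <- c(glucose_level = "value", meal = "carbs", bolus = "dose")

#' Read a patient file in the Ohio T1DM XML dialect
#'
#' Parses glucose, meal and bolus events from one train or test file.
#' Glucose readings are returned as an irregular point series; grid
#' regularization happens downstream in [regularize_grid()]. No values
#' are invented and the reader never emits provenance other than
#' `observed`. Timestamps are parsed strictly as `DD-MM-YYYY HH:MM:SS`.
#'
#' @param path Path to an XML file.
#' @param role Which slot of the returned record the glucose series
#'   fills: `"train"` or `"test"`. The other slot is left empty.
#' @return A [patient_record()].
#' @seealso [write_ohio_xml()], [read_ohio_patient()]
#' @export
read_ohio_xml <- function(path, role = c("train", "test")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed XML in ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  root <- xml2::xml_name(doc)
  if (root != "patient") {
    stop("expected root element <patient>, found <", root, ">", call. = FALSE)
  }
  patient_id <- xml2::xml_attr(doc, "id")
  if (is.na(patient_id)) patient_id <- "unknown"

  read_container <- function(name) {
    node <- xml2::xml_find_first(doc, paste0("./", name))
    if (inherits(node, "xml_missing")) {
      return(list(times = as.POSIXct(character(), tz = "UTC"),
                  values = numeric()))
    }
    events <- xml2::xml_find_all(node, "./event")
    ts <- xml2::xml_attr(events, "ts")
    val <- xml2::xml_attr(events, OHIO_VALUE_ATTR[[name]])
    if (anyNA(ts) || anyNA(val)) {
      stop("<", name, "> event missing 'ts' or '", OHIO_VALUE_ATTR[[name]],
           "' attribute", call. = FALSE)
    }
    times <- parse_ohio_time(ts)
    values <- suppressWarnings(as.numeric(val))
    if (anyNA(values)) {
      stop("<", name, "> event with non-numeric ", OHIO_VALUE_ATTR[[name]],
           call. = FALSE)
    }
    if (length(times) > 1L) {
      d <- diff(as.numeric(times))
      if (any(d <= 0)) {
        stop("<", name, "> timestamps not strictly increasing at event(s) ",
             paste(which(d <= 0) + 1L, collapse = ", "), call. = FALSE)
      }
    }
    list(times = times, values = values)
  }

  known <- c("glucose_level", "meal", "bolus")
  others <- setdiff(xml2::xml_name(xml2::xml_children(doc)), known)
  if (length(others)) {
    warning("ignoring container(s) with no pipeline semantics: ",
            paste(unique(others), collapse = ", "), call. = FALSE)
  }

  glucose <- read_container("glucose_level")
  meal <- read_container("meal")
  bolus <- read_container("bolus")
  cgm <- irregular_series(glucose$times, glucose$values)
  empty <- irregular_series(as.POSIXct(character(), tz = "UTC"), numeric())
  patient_record(
    patient_id = patient_id,
    train_cgm = if (role == "train") cgm else empty,
    test_cgm = if (role == "test") cgm else empty,
    meals = event_series("meal", meal$times, meal$values),
    boluses = event_series("bolus", bolus$times, bolus$values)
  )
}

#' Read a patient's train and test files into one record
#'
#' @param train_path,test_path Paths to the train and test XML files.
#' @return A [patient_record()] with both CGM slots filled and the event
#'   logs merged (event times across the two files must interleave
#'   consistently; duplicates are not merged).
#' @export
read_ohio_patient <- function(train_path, test_path) {
  tr <- read_ohio_xml(train_path, role = "train")
  te <- read_ohio_xml(test_path, role = "test")
  merge_events <- function(a, b, kind) {
    times <- c(a$times, b$times)
    mags <- c(a$magnitudes, b$magnitudes)
    o <- order(times)
    event_series(kind, times[o], mags[o])
  }
  patient_record(
    patient_id = tr$patient_id,
    train_cgm = tr$train_cgm, test_cgm = te$test_cgm,
    meals = merge_events(tr$meals, te$meals, "meal"),
    boluses = merge_events(tr$boluses, te$boluses, "bolus")
  )
}

#' Write a patient record in the Ohio T1DM XML dialect
#'
#' Writes one role's CGM series plus the events belonging to that
#' segment (train: everything up to the series end; test: everything
#' from the series start), such that `read_ohio_xml()` reproduces
#' times, values and magnitudes exactly and
#' [read_ohio_patient()] on a written train/test pair recovers the full
#' event logs without duplication. Values are serialized with full
#' double precision.
#'
#' @param record A [patient_record()].
#' @param path Output file path.
#' @param role Which CGM series to write (`"train"` or `"test"`).
#' @return Invisibly, `path`.
#' @export
write_ohio_xml <- function(record, path, role = c("train", "test")) {
  role <- match.arg(role)
  stopifnot(inherits(record, "patient_record"))
  cgm <- if (role == "train") record$train_cgm else record$test_cgm
  if (inherits(cgm, "sampled_series")) {
    keep <- is.finite(cgm$values)
    cgm <- irregular_series(grid_times(cgm$grid)[keep], cgm$values[keep])
  }
  keep_event <- function(times) {
    if (length(cgm$times) == 0L) return(rep(TRUE, length(times)))
    if (role == "train") times <= max(cgm$times) else times >= min(cgm$times)
  }
  container <- function(name, times, values) {
    sel <- keep_event(times)
    events <- sprintf('  <event ts="%s" %s="%.17g"/>',
                      format_ohio_time(times[sel]), OHIO_VALUE_ATTR[[name]],
                      values[sel])
    c(sprintf(" <%s>", name), events, sprintf(" </%s>", name))
  }
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             sprintf('<patient id="%s">', record$patient_id),
             container("glucose_level", cgm$times, cgm$values),
             container("meal", record$meals$times, record$meals$magnitudes),
             container("bolus", record$boluses$times, record$boluses$magnitudes),
             "</patient>")
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write ", path, call. = FALSE)
  invisible(path)
}
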