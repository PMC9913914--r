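# Fixture builders shared across the test files. Everything is
# generated in code; no binary fixtures.

T0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")

# A small fully observed CGM series on the 5-minute grid.
make_cgm <- function(values, start = T0, provenance = "observed") {
  sampled_series(grid_spec(start, length(values), 5), values, provenance)
}

# A minimal valid preprocessed record: smooth-ish train and test CGM on
# adjacent grids, one meal and one bolus inside the train span.
make_small_record <- function(n_train = 60, n_test = 30) {
  tr_vals <- 120 + 10 * sin(seq_len(n_train) / 7)
  te_start <- T0 + n_train * 300
  te_vals <- 120 + 10 * sin((n_train + seq_len(n_test)) / 7)
  patient_record(
    patient_id = "fixture-1",
    train_cgm = make_cgm(tr_vals),
    test_cgm = make_cgm(te_vals, start = te_start),
    meals = event_series("meal", T0 + 3600, 45),
    boluses = event_series("bolus", T0 + 3600 - 900, 4)
  )
}

# Record with empty event logs.
make_eventless_record <- function(n_train = 60, n_test = 30) {
  r <- make_small_record(n_train, n_test)
  r$meals <- event_series("meal")
  r$boluses <- event_series("bolus")
  r
}

# Random valid irregular record for round-trip property tests.
random_record <- function(seed, n_cgm = 50, n_meals = 3) {
  withr::with_seed(seed, {
    cgm_times <- T0 + cumsum(sample(c(300, 300, 300, 600), n_cgm,
                                    replace = TRUE))
    cgm_vals <- round(runif(n_cgm, 60, 300), 1)
    span <- range(as.numeric(cgm_times))
    meal_times <- sort(sample(seq(span[1], span[2], by = 60), n_meals))
    meal_g <- round(runif(n_meals, 20, 90))
    patient_record(
      patient_id = sprintf("rand-%d", seed),
      train_cgm = irregular_series(cgm_times, cgm_vals),
      test_cgm = irregular_series(as.POSIXct(character(), tz = "UTC"),
                                  numeric()),
      meals = event_series("meal", as.POSIXct(meal_times, tz = "UTC",
                                              origin = "1970-01-01"), meal_g),
      boluses = event_series("bolus",
                             as.POSIXct(meal_times - 900, tz = "UTC",
                                        origin = "1970-01-01"),
                             round(meal_g * 0.1, 1))
    )
  })
}

# Flatten / unflatten nested parameter lists (for gradient checks).
flatten_params <- function(p) {
  if (is.list(p)) return(unlist(lapply(p, flatten_params), use.names = FALSE))
  as.numeric(p)
}

set_flat_params <- function(p, flat) {
  i <- 0L
  walk <- function(q) {
    if (is.list(q)) return(lapply(q, walk))
    n <- length(q)
    out <- q
    out[] <- flat[(i + 1L):(i + n)]
    i <<- i + n
    out
  }
  walk(p)
}
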