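test_that("identical seeds give elementwise-identical records", {
  a <- simulate_patient(simulation_config(seed = 7, days = 14))
  b <- simulate_patient(simulation_config(seed = 7, days = 14))
  expect_identical(a$train_cgm$values, b$train_cgm$values)
  expect_identical(a$test_cgm$values, b$test_cgm$values)
  expect_identical(a$train_cgm$provenance, b$train_cgm$provenance)
  expect_identical(a$meals$times, b$meals$times)
  expect_identical(a$boluses$magnitudes, b$boluses$magnitudes)
  c_ <- simulate_patient(simulation_config(seed = 8, days = 14))
  expect_false(identical(a$train_cgm$values, c_$train_cgm$values))
})

test_that("degenerate configurations are rejected", {
  expect_error(simulation_config(days = 0), ">= 1")
  expect_error(simulate_patient(simulation_config(days = 3)), "test series")
  expect_error(simulation_config(ar_coeff = 1), "\\[0, 1\\)")
  expect_error(simulation_config(noise_sd_mgdl = -1), ">= 0")
})

test_that("disabling gaps and spikes yields a fully observed record", {
  r <- simulate_patient(simulation_config(seed = 2, days = 7,
                                          gap_rate_per_day = 0,
                                          spike_prob = 0))
  expect_true(all(r$train_cgm$provenance == "observed"))
  expect_true(all(r$test_cgm$provenance == "observed"))
  expect_false(anyNA(r$train_cgm$values))
  gt <- ground_truth_components(r)
  expect_equal(gt$spikes$values, rep(0, length(gt$spikes)))
})

test_that("simulated records satisfy the record invariants", {
  for (seed in c(1, 4)) {
    r <- simulate_patient(simulation_config(seed = seed, days = 10))
    expect_identical(validate_record(r), character(0))
    # last 20 % of days form the test segment
    expect_equal(length(r$test_cgm), 2 * 288)
    expect_equal(length(r$train_cgm) + length(r$test_cgm), 10 * 288)
    # boluses precede their meals by 15 min
    expect_equal(as.numeric(r$meals$times - r$boluses$times, units = "mins"),
                 rep(15, length(r$meals$times)))
    # gap runs never touch segment boundaries, so imputation can bracket
    expect_equal(r$train_cgm$provenance[1], "observed")
    expect_equal(tail(r$train_cgm$provenance, 1), "observed")
    expect_equal(r$test_cgm$provenance[1], "observed")
    expect_equal(tail(r$test_cgm$provenance, 1), "observed")
    expect_true(all(r$train_cgm$values >= 40 & r$train_cgm$values <= 400,
                    na.rm = TRUE))
  }
})

test_that("ground-truth components sum to the pre-clip CGM exactly", {
  r <- simulate_patient(simulation_config(seed = 11, days = 7))
  gt <- ground_truth_components(r)
  total <- gt$baseline$values + gt$circadian$values + gt$meal_effect$values +
    gt$insulin_effect$values + gt$ar_noise$values + gt$spikes$values
  expect_equal(total, gt$preclip$values)
  expect_error(ground_truth_components(make_small_record()),
               "simulate_patient")
})

test_that("a zero-meal configuration has an identically zero meal component", {
  r <- simulate_patient(simulation_config(seed = 3, days = 7,
                                          meal_rate_per_day = 0))
  gt <- ground_truth_components(r)
  expect_equal(gt$meal_effect$values, rep(0, length(gt$meal_effect)))
  expect_length(r$meals$times, 0)
})

test_that("a single meal's effect peaks at carb_gain * grams", {
  cfg <- simulation_config(seed = 13, days = 7, meal_rate_per_day = 0,
                           gap_rate_per_day = 0, spike_prob = 0)
  r <- simulate_patient(cfg)
  # inject one 60 g meal by re-running the transform the simulator uses
  g <- attr(r, "ground_truth")$grid
  meal <- event_series("meal", T0 + 6 * 3600, 60)
  effect <- cfg$carb_gain_mgdl_per_g * operative_carbs_series(meal, g)$values
  expect_equal(max(effect), cfg$carb_gain_mgdl_per_g * 60 *
                 max(carb_curve_single(0:48, 60)) / 60)
  expect_equal(max(effect), 2.5 * 60)
})

test_that("CGM variance matches the AR(1) + circadian closed form without events", {
  cfg <- simulation_config(seed = 17, days = 60, meal_rate_per_day = 0,
                           carb_gain_mgdl_per_g = 0,
                           insulin_gain_mgdl_per_u = 0,
                           gap_rate_per_day = 0, spike_prob = 0)
  r <- simulate_patient(cfg)
  x <- c(r$train_cgm$values, r$test_cgm$values)
  expected <- cfg$noise_sd_mgdl^2 / (1 - cfg$ar_coeff^2) +
    cfg$circadian_amp_mgdl^2 / 2
  expect_equal(var(x), expected, tolerance = 0.2)
})

test_that("gap fraction converges to its configured expectation", {
  cfg <- simulation_config(seed = 19, days = 60, spike_prob = 0)
  r <- simulate_patient(cfg)
  frac <- mean(c(r$train_cgm$provenance, r$test_cgm$provenance) ==
                 "inserted_missing")
  expected <- cfg$gap_rate_per_day * mean(cfg$gap_len_range) /
    288           # per-day expected missing samples over samples per day
  expect_equal(frac, expected, tolerance = 0.2)
})
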