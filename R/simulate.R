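# Seeded synthetic type 1 diabetes patient generator. Produces CGM on a
# 5-minute grid as baseline + circadian sinusoid + meal-driven rises +
# bolus-driven falls + AR(1) sensor noise + occasional spikes, clipped
# to the sensor range, with sensor-change gaps and matching meal/bolus
# event logs. The meal and insulin kernels reuse the physiological
# feature curves so that multivariate feature configurations are
# informative by construction.

#' Synthetic patient simulation configuration
#'
#' Defaults describe a realistic adult on rapid-acting insulin: ~3.5
#' meals/day of 20-90 g carbs eaten during waking hours, a bolus ~15 min
#' before each meal dosed at 0.1 U/g, meal rises of 2.5 mg/dL per gram,
#' insulin falls of 35 mg/dL per unit, a 15 mg/dL circadian swing,
#' AR(1) sensor noise (innovation sd 3 mg/dL, coefficient 0.95), about
#' one sensor gap every two days of 10 min-2 h, and rare 40 mg/dL
#' spike artifacts.
#'
#' @param seed Integer RNG seed.
#' @param days Simulated days (5-min grid, 288 samples/day).
#' @param baseline_mgdl Baseline glucose (mg/dL).
#' @param circadian_amp_mgdl Circadian sinusoid amplitude (mg/dL).
#' @param ar_coeff AR(1) coefficient in `[0, 1)`.
#' @param noise_sd_mgdl AR(1) innovation standard deviation (mg/dL).
#' @param meal_rate_per_day Mean meals per day (Poisson).
#' @param carb_range_g Meal size range in grams, `c(min, max)`.
#' @param carb_gain_mgdl_per_g Glucose rise per gram of operative carbs.
#' @param bolus_ratio_u_per_g Bolus dose per gram of meal carbs.
#' @param insulin_gain_mgdl_per_u Glucose fall per unit at peak insulin
#'   activity.
#' @param gap_rate_per_day Mean sensor gaps per day (Poisson).
#' @param gap_len_range Gap length range in samples, `c(min, max)`.
#' @param spike_prob Per-sample probability of a spike artifact.
#' @param spike_amp_mgdl Spike amplitude (mg/dL, random sign).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, days = 14, baseline_mgdl = 120,
                              circadian_amp_mgdl = 15, ar_coeff = 0.95,
                              noise_sd_mgdl = 3, meal_rate_per_day = 3.5,
                              carb_range_g = c(20, 90),
                              carb_gain_mgdl_per_g = 2.5,
                              bolus_ratio_u_per_g = 0.1,
                              insulin_gain_mgdl_per_u = 35,
                              gap_rate_per_day = 0.5,
                              gap_len_range = c(2, 24),
                              spike_prob = 0.005, spike_amp_mgdl = 40) {
  cfg <- list(seed = as.integer(seed), days = days,
              baseline_mgdl = baseline_mgdl,
              circadian_amp_mgdl = circadian_amp_mgdl,
              ar_coeff = ar_coeff, noise_sd_mgdl = noise_sd_mgdl,
              meal_rate_per_day = meal_rate_per_day,
              carb_range_g = carb_range_g,
              carb_gain_mgdl_per_g = carb_gain_mgdl_per_g,
              bolus_ratio_u_per_g = bolus_ratio_u_per_g,
              insulin_gain_mgdl_per_u = insulin_gain_mgdl_per_u,
              gap_rate_per_day = gap_rate_per_day,
              gap_len_range = gap_len_range,
              spike_prob = spike_prob, spike_amp_mgdl = spike_amp_mgdl)
  rates <- c(cfg$circadian_amp_mgdl, cfg$noise_sd_mgdl, cfg$meal_rate_per_day,
             cfg$carb_gain_mgdl_per_g, cfg$bolus_ratio_u_per_g,
             cfg$insulin_gain_mgdl_per_u, cfg$gap_rate_per_day,
             cfg$spike_prob, cfg$spike_amp_mgdl)
  if (any(rates < 0)) stop("rates and amplitudes must be >= 0", call. = FALSE)
  if (cfg$ar_coeff < 0 || cfg$ar_coeff >= 1) {
    stop("`ar_coeff` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(cfg$days) || cfg$days < 1) {
    stop("`days` must be >= 1", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

SIM_CLIP_RANGE <- c(40, 400)   # CGM sensor dynamic range, mg/dL
SAMPLES_PER_DAY <- 288L

#' Simulate a synthetic patient record
#'
#' Generates a seeded [patient_record()] on a 5-minute grid. The CGM is
#' baseline + circadian sinusoid + sum of meal effects (operative-carbs
#' kernel, unit peak, scaled by `carb_gain * grams`) - sum of bolus
#' effects (insulin activity kernel, unit peak, scaled by
#' `insulin_gain * dose`) + AR(1) noise + spikes, clipped to 40-400
#' mg/dL. Sensor gaps are injected as `inserted_missing` runs (never
#' touching a segment boundary, so gaps stay bracketed). The last 20 %
#' of days form the test series. Identical seeds give identical records.
#'
#' @param config A [simulation_config()].
#' @param carb_params A [carb_kinetics_params()].
#' @param insulin_params An [insulin_kinetics_params()].
#' @return A [patient_record()] carrying latent ground-truth components
#'   retrievable with [ground_truth_components()].
#' @export
simulate_patient <- function(config = simulation_config(),
                             carb_params = carb_kinetics_params(),
                             insulin_params = insulin_kinetics_params()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- as.integer(round(config$days * SAMPLES_PER_DAY))
  if (floor(config$days * 0.2) < 1) {
    stop("need at least 5 simulated days so the last 20 % of days forms ",
         "a non-empty test series", call. = FALSE)
  }
  start <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")
  grid <- grid_spec(start, n, 5)
  t_mins <- (seq_len(n) - 1L) * 5

  withr::with_seed(config$seed, {
    # circadian: lowest pre-dawn, peaking late afternoon
    circadian <- config$circadian_amp_mgdl *
      sin(2 * pi * (t_mins / 60 - 10) / 24)

    # AR(1) noise, initialized from the stationary distribution
    innov <- rnorm(n, 0, config$noise_sd_mgdl)
    ar <- numeric(n)
    ar[1] <- if (config$ar_coeff > 0 && config$noise_sd_mgdl > 0) {
      rnorm(1, 0, config$noise_sd_mgdl / sqrt(1 - config$ar_coeff^2))
    } else innov[1]
    for (k in 2:n) ar[k] <- config$ar_coeff * ar[k - 1] + innov[k]

    # meals across waking hours (07:00-22:00), whole-second times
    meal_times <- numeric(); meal_grams <- numeric()
    for (d in seq_len(ceiling(config$days)) - 1L) {
      n_meals <- rpois(1, config$meal_rate_per_day)
      if (n_meals == 0L) next
      secs <- sort(round(runif(n_meals, 7 * 3600, 22 * 3600)))
      secs <- secs[!duplicated(secs)]
      meal_times <- c(meal_times, d * 86400 + secs)
      meal_grams <- c(meal_grams,
                      round(runif(length(secs), config$carb_range_g[1],
                                  config$carb_range_g[2])))
    }
    keep <- meal_times < n * 300
    meal_times <- meal_times[keep]; meal_grams <- meal_grams[keep]
    meals <- event_series("meal", start + meal_times, pmax(meal_grams, 1))
    bolus_doses <- round(config$bolus_ratio_u_per_g * meals$magnitudes, 1)
    boluses <- event_series("bolus", meals$times - 15 * 60,
                            pmax(bolus_doses, 0.1))

    # meal effect: operative-carbs kernel has unit peak per gram
    meal_effect <- config$carb_gain_mgdl_per_g *
      operative_carbs_series(meals, grid, carb_params)$values

    # insulin effect: unit-peak activity kernel scaled by gain * dose
    act <- insulin_activity_curve(insulin_params, resolution_mins = 5)
    kernel <- act$activity / max(act$activity)
    insulin_effect <- -config$insulin_gain_mgdl_per_u *
      superpose_events(boluses, grid,
                       function(k, mag) mag * kernel[pmin(k, length(kernel) - 1L) + 1L],
                       support_samples = length(kernel) - 1L)$values

    # spike artifacts
    spikes <- numeric(n)
    hit <- which(rbinom(n, 1, config$spike_prob) == 1L)
    if (length(hit)) {
      spikes[hit] <- config$spike_amp_mgdl * sample(c(-1, 1), length(hit),
                                                    replace = TRUE)
    }

    preclip <- config$baseline_mgdl + circadian + meal_effect +
      insulin_effect + ar + spikes
    cgm <- pmin(pmax(preclip, SIM_CLIP_RANGE[1]), SIM_CLIP_RANGE[2])

    # sensor gaps: runs of inserted_missing, kept clear of segment edges
    # (train = rows 1..split_at, test = the last 20 % of days)
    split_at <- n - as.integer(floor(config$days * 0.2)) * SAMPLES_PER_DAY
    prov <- rep("observed", n)
    n_gaps <- rpois(1, config$gap_rate_per_day * config$days)
    protected <- c(1L, split_at, split_at + 1L, n)
    for (g in seq_len(n_gaps)) {
      len <- sample(config$gap_len_range[1]:config$gap_len_range[2], 1)
      s0 <- sample(2L:(n - len - 1L), 1)
      run <- s0:(s0 + len - 1L)
      if (any(run %in% protected)) next
      if (all(run <= split_at) || all(run > split_at)) prov[run] <- "inserted_missing"
    }
    vals <- cgm
    vals[prov == "inserted_missing"] <- NA_real_
  })

  train_idx <- seq_len(split_at)
  test_idx <- (split_at + 1L):n
  mk_series <- function(idx) {
    sampled_series(grid_spec(grid_times(grid)[idx[1]], length(idx), 5),
                   vals[idx], prov[idx])
  }
  record <- patient_record(
    patient_id = sprintf("sim-%03d", config$seed %% 1000L),
    train_cgm = mk_series(train_idx), test_cgm = mk_series(test_idx),
    meals = meals, boluses = boluses
  )
  attr(record, "ground_truth") <- list(
    baseline = rep(config$baseline_mgdl, n),
    circadian = circadian, meal_effect = meal_effect,
    insulin_effect = insulin_effect, ar_noise = ar, spikes = spikes,
    preclip = preclip, grid = grid, config = config
  )
  record
}

#' Latent components of a simulated record
#'
#' Returns the circadian, meal-effect, insulin-effect, AR-noise and
#' spike components used by [simulate_patient()], as [sampled_series()]
#' on the full simulation grid, plus the pre-clip CGM (`preclip`) and
#' constant `baseline`. The components plus baseline sum to `preclip`
#' exactly; clipping and gap insertion are applied afterwards.
#'
#' @param record A record produced by [simulate_patient()].
#' @return Named list of [sampled_series()] (and the `baseline` series).
#' @export
ground_truth_components <- function(record) {
  gt <- attr(record, "ground_truth")
  if (is.null(gt)) {
    stop("record was not produced by simulate_patient()", call. = FALSE)
  }
  comps <- c("baseline", "circadian", "meal_effect", "insulin_effect",
             "ar_noise", "spikes", "preclip")
  out <- lapply(comps, function(nm) sampled_series(gt$grid, gt[[nm]]))
  names(out) <- comps
  out
}
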