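# Event-to-continuous feature transforms: operative carbohydrates from
# meal events, and active insulin from bolus events via the exponential
# insulin-on-board (IOB) model.

#' Carbohydrate absorption kinetics parameters
#'
#' Parameters of the piecewise operative-carbs curve on a sample-indexed
#' grid: the curve is zero for the first `delay_samples` samples after a
#' meal (no glycemic effect for ~15 min), rises by `alpha_inc * c_meal`
#' per sample until it saturates at the full meal size by `peak_sample`
#' (60 min at 5-min sampling), then decays by `alpha_dec * c_meal` per
#' sample, reaching zero at `end_sample` (3 h after the peak).
#'
#' @param alpha_inc Rising rate, fraction of the meal per sample
#'   (default 0.111, i.e. 11.1 %/sample).
#' @param alpha_dec Decay rate, fraction of the meal per sample
#'   (default 0.028, i.e. 2.8 %/sample).
#' @param delay_samples Samples with zero operative carbs after the meal
#'   (default 3).
#' @param peak_sample Sample index at which the curve saturates
#'   (default 12).
#' @param end_sample Sample index at/after which the curve is zero
#'   (default 48).
#' @param interval_mins Sampling interval in minutes (default 5).
#' @return An object of class `carb_kinetics_params`.
#' @export
carb_kinetics_params <- function(alpha_inc = 0.111, alpha_dec = 0.028,
                                 delay_samples = 3, peak_sample = 12,
                                 end_sample = 48, interval_mins = 5) {
  stopifnot(alpha_inc > 0, alpha_inc <= 1, alpha_dec > 0, alpha_dec <= 1,
            interval_mins > 0)
  delay_samples <- as.integer(delay_samples)
  peak_sample <- as.integer(peak_sample)
  end_sample <- as.integer(end_sample)
  if (!(delay_samples < peak_sample && peak_sample < end_sample)) {
    stop("need delay_samples < peak_sample < end_sample", call. = FALSE)
  }
  structure(list(alpha_inc = alpha_inc, alpha_dec = alpha_dec,
                 delay_samples = delay_samples, peak_sample = peak_sample,
                 end_sample = end_sample, interval_mins = interval_mins),
            class = "carb_kinetics_params")
}

#' Operative carbohydrates for a single meal
#'
#' Evaluates the piecewise absorption curve at integer sample offsets
#' `k` since the meal: 0 during the delay; `(k - delay + 1) * alpha_inc
#' * c_meal` while rising; `(1 - (k - peak) * alpha_dec) * c_meal` while
#' decaying; 0 at and beyond `end_sample`. The result is clamped to
#' `[0, c_meal]`, which absorbs the sub-percent round-off in the printed
#' rates (9 * 0.111 and 36 * 0.028 are not exactly 1).
#'
#' @param k Integer sample offset(s) since the meal (>= 0; vectorized).
#' @param c_meal Meal size in grams (> 0).
#' @param params A [carb_kinetics_params()].
#' @return Operative carbs in grams, same length as `k`.
#' @export
carb_curve_single <- function(k, c_meal, params = carb_kinetics_params()) {
  stopifnot(inherits(params, "carb_kinetics_params"), c_meal > 0)
  if (any(k < 0)) stop("sample offset `k` must be >= 0", call. = FALSE)
  k <- as.integer(k)
  out <- numeric(length(k))
  rising <- k >= params$delay_samples & k < params$peak_sample
  out[rising] <- (k[rising] - params$delay_samples + 1) * params$alpha_inc * c_meal
  decaying <- k >= params$peak_sample & k < params$end_sample
  out[decaying] <- (1 - (k[decaying] - params$peak_sample) * params$alpha_dec) * c_meal
  pmin(pmax(out, 0), c_meal)
}

#' Operative-carbs series from a meal log
#'
#' Transforms event-based meal records into a continuous feature: each
#' grid slot holds the superposed [carb_curve_single()] contributions of
#' all meals, with each meal snapped to its nearest grid slot so sample
#' offsets stay integral. Slots before every meal are zero.
#'
#' @param meals A [event_series()] of kind `"meal"`.
#' @param grid A [grid_spec()].
#' @param params A [carb_kinetics_params()].
#' @return A [sampled_series()] in grams with provenance `observed`.
#' @export
operative_carbs_series <- function(meals, grid, params = carb_kinetics_params()) {
  stopifnot(inherits(meals, "event_series"), meals$kind == "meal",
            inherits(grid, "grid_spec"))
  superpose_events(meals, grid,
                   function(k, mag) carb_curve_single(k, mag, params),
                   support_samples = params$end_sample)
}

#' Exponential-decay shape parameters for the IOB model
#'
#' Derives the decay time constant `tau`, rise-time factor `a` and
#' auxiliary scale `S` from the insulin peak time `tp` and the duration
#' of insulin action `td`:
#' `tau = tp * (1 - tp/td) / (1 - 2*tp/td)`, `a = 2*tau/td`,
#' `S = 1 / (1 - a + (1 + a) * exp(-td/tau))`.
#'
#' @param tp Peak time of insulin activity in minutes (0 < tp < td/2).
#' @param td Duration of insulin action in minutes.
#' @return A list with components `tau`, `a`, `S`.
#' @export
insulin_shape_params <- function(tp, td) {
  stopifnot(tp > 0, td > 0)
  if (tp >= td / 2) {
    stop("peak time `tp` must be below td/2: the shape denominator ",
         "1 - 2*tp/td is singular at tp = td/2", call. = FALSE)
  }
  tau <- tp * (1 - tp / td) / (1 - 2 * tp / td)
  a <- 2 * tau / td
  S <- 1 / (1 - a + (1 + a) * exp(-td / tau))
  list(tau = tau, a = a, S = S)
}

#' Insulin kinetics parameters
#'
#' Rapid-acting insulin presets: `"adult"` peaks at 75 min, `"child"`
#' at 65 min, both with a 6-hour duration of insulin action by default.
#' `tau`, `a` and `S` are recomputed from `(tp, td)` on construction.
#'
#' @param tp Peak time in minutes, or use `preset`.
#' @param td Duration of insulin action in minutes (default 360).
#' @param preset Optional `"adult"` or `"child"`; overrides `tp`.
#' @return An object of class `insulin_kinetics_params`.
#' @export
insulin_kinetics_params <- function(tp = 75, td = 360, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("adult", "child"))
    tp <- c(adult = 75, child = 65)[[preset]]
  }
  shape <- insulin_shape_params(tp, td)
  structure(c(list(tp = tp, td = td), shape),
            class = "insulin_kinetics_params")
}

#' Insulin-on-board fraction
#'
#' Fraction of a bolus still active `t` minutes after injection under
#' the exponential IOB model:
#' `IOB(t) = 1 - S*(1-a)*[(t^2/(tau*td*(1-a)) - t/tau - 1)*exp(-t/tau) + 1]`
#' for `0 <= t <= td`, and 0 beyond `td`. Equals 1 at `t = 0`, decreases
#' monotonically, and reaches exactly 0 at `t = td`.
#'
#' @param t Minutes since the bolus (>= 0; vectorized).
#' @param params An [insulin_kinetics_params()].
#' @return IOB fraction(s) in `[0, 1]`.
#' @export
iob_fraction <- function(t, params = insulin_kinetics_params()) {
  stopifnot(inherits(params, "insulin_kinetics_params"))
  if (any(t < 0)) stop("time since bolus must be >= 0", call. = FALSE)
  tau <- params$tau; a <- params$a; S <- params$S; td <- params$td
  inner <- (t^2 / (tau * td * (1 - a)) - t / tau - 1) * exp(-t / tau) + 1
  out <- 1 - S * (1 - a) * inner
  out[t > td] <- 0
  pmin(pmax(out, 0), 1)
}

#' Insulin activity curve
#'
#' Numerical insulin activity (the negative time derivative of
#' [iob_fraction()]) by central differences on a fine grid; its argmax
#' locates the preset's peak time.
#'
#' @param params An [insulin_kinetics_params()].
#' @param resolution_mins Grid resolution in minutes (default 1).
#' @return A data.frame with columns `t` (minutes) and `activity`
#'   (fraction per minute).
#' @export
insulin_activity_curve <- function(params = insulin_kinetics_params(),
                                   resolution_mins = 1) {
  t <- seq(0, params$td, by = resolution_mins)
  iob <- iob_fraction(t, params)
  n <- length(t)
  act <- numeric(n)
  act[2:(n - 1)] <- (iob[1:(n - 2)] - iob[3:n]) / (2 * resolution_mins)
  act[1] <- (iob[1] - iob[2]) / resolution_mins
  act[n] <- (iob[n - 1] - iob[n]) / resolution_mins
  data.frame(t = t, activity = act)
}

#' Active-insulin series from a bolus log
#'
#' Transforms bolus events into a continuous feature: each grid slot
#' holds the sum over boluses of `dose * iob_fraction(slot time - bolus
#' time)`, with boluses snapped to their nearest grid slot. A 4 U bolus
#' contributes 4.0 at its own slot, decaying to 0 by the duration of
#' insulin action.
#'
#' @param boluses A [event_series()] of kind `"bolus"`.
#' @param grid A [grid_spec()].
#' @param params An [insulin_kinetics_params()].
#' @return A [sampled_series()] in insulin units.
#' @export
active_insulin_series <- function(boluses, grid,
                                  params = insulin_kinetics_params()) {
  stopifnot(inherits(boluses, "event_series"), boluses$kind == "bolus",
            inherits(grid, "grid_spec"))
  support <- ceiling(params$td / grid$interval_mins) + 1L
  superpose_events(boluses, grid,
                   function(k, mag) mag * iob_fraction(k * grid$interval_mins, params),
                   support_samples = support)
}

# Shared superposition: snap each event to its nearest grid slot and add
# kernel(k, magnitude) over the kernel's support. Events snapped before
# the grid contribute their tail; events after the grid end are ignored.
superpose_events <- function(events, grid, kernel, support_samples) {
  values <- numeric(grid$n_samples)
  if (grid$n_samples == 0L || length(events$times) == 0L) {
    return(sampled_series(grid, values))
  }
  slot <- as.integer(round(as.numeric(events$times - grid$start_time,
                                      units = "mins") / grid$interval_mins))
  for (i in seq_along(slot)) {
    s0 <- slot[i]
    if (s0 >= grid$n_samples) next
    k_lo <- max(0L, -s0)
    k_hi <- min(support_samples, grid$n_samples - 1L - s0)
    if (k_hi < k_lo) next
    k <- k_lo:k_hi
    idx <- s0 + k + 1L
    values[idx] <- values[idx] + kernel(k, events$magnitudes[i])
  }
  sampled_series(grid, values)
}
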