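# Discrete setpoint-tracking controller.
#
# The pump control loop is a bang-bang increment controller: at each control
# tick the executed rotation is compared with the rotation setpoint; the
# integer motor speed is nudged by +/- 1% (held when they match exactly) and
# clamped to its bounds. Within a tick the rate is constant, so integration
# is exact and no ODE machinery is needed.

#' Controller settings
#'
#' @param dt_control control interval (s), > 0. Speed adjustments happen at
#'   this cadence; the observed oscillation around the setpoint has a period
#'   of a few ticks.
#' @param speed_step speed adjustment per tick (%, positive integer).
#' @param speed_init starting speed (%).
#' @param speed_min,speed_max clamp bounds (%); `speed_min` must not be
#'   below the motor's dead zone, where the response is non-linear.
#' @param allow_stop if `TRUE`, a decrement below `speed_min` switches the
#'   motor off (speed 0) instead of holding `speed_min`, and an increment
#'   from 0 re-engages at `speed_min`. This duty-cycling lets the
#'   controller track setpoint flows below the 5%-speed flow; with the
#'   default `FALSE`, such setpoints are oversupplied at `speed_min` and
#'   flagged.
#' @return An object of class `controller_settings`.
#' @examples
#' controller_settings()
#' @export
controller_settings <- function(dt_control = 1, speed_step = 1, speed_init = 5,
                                speed_min = 5, speed_max = 100,
                                allow_stop = FALSE) {
  if (!is.numeric(dt_control) || length(dt_control) != 1 || dt_control <= 0)
    pf_validation_stop("`dt_control` must be a single positive number of seconds")
  if (!is.numeric(speed_step) || length(speed_step) != 1 ||
      speed_step < 1 || speed_step != round(speed_step))
    pf_validation_stop("`speed_step` must be a positive integer (%)")
  if (!is.numeric(speed_min) || !is.numeric(speed_max) ||
      speed_min < 0 || speed_max > 100 || speed_min > speed_max)
    pf_validation_stop("need 0 <= speed_min <= speed_max <= 100")
  if (!is.numeric(speed_init) || length(speed_init) != 1 ||
      speed_init < 0 || speed_init > speed_max)
    pf_validation_stop("`speed_init` must lie in [0, speed_max]")
  structure(list(dt_control = dt_control, speed_step = as.integer(speed_step),
                 speed_init = as.integer(round(speed_init)),
                 speed_min = as.integer(round(speed_min)),
                 speed_max = as.integer(round(speed_max)),
                 allow_stop = isTRUE(allow_stop)),
            class = "controller_settings")
}

#' Motor rotation rate at a commanded speed
#'
#' Linear speed-to-rate model: `rate = gain * speed` degrees s^-1 for
#' speeds at or above the dead zone. A speed of exactly 0 is off. Speeds
#' strictly between 0 and the dead zone are in the non-linear regime that
#' is not modelled: the rate is returned as 0 with a warning. Speeds above
#' 100 are clamped with a warning, or rejected in strict mode.
#'
#' @param speed commanded speed (%-speed); vectorised.
#' @param motor a [motor_calibration()].
#' @param strict error instead of clamping on speeds above 100.
#' @return Rotation rate in degrees s^-1.
#' @examples
#' motor_rate(100, motor_calibration()) # 852.34
#' @export
motor_rate <- function(speed, motor = motor_calibration(), strict = FALSE) {
  if (!inherits(motor, "motor_calibration"))
    pf_validation_stop("`motor` must be a motor_calibration")
  if (!is.numeric(speed) || any(!is.finite(speed)) || any(speed < 0))
    pf_validation_stop("`speed` must be non-negative and finite (%)")
  if (any(speed > 100)) {
    if (strict) pf_validation_stop("speed above 100% is not allowed in strict mode")
    warning("speed above 100% clamped to 100%", call. = FALSE)
    speed <- pmin(speed, 100)
  }
  dead <- speed > 0 & speed < motor$dead_zone
  if (any(dead))
    warning("speeds below the dead zone respond non-linearly; returning rate 0",
            call. = FALSE)
  rate <- motor$gain * speed
  rate[dead | speed == 0] <- 0
  rate
}

#' Simulate the setpoint-tracking controller
#'
#' Replays a compiled rotation schedule through the discrete controller: at
#' each tick of `dt_control` seconds the accumulated rotation is compared
#' with the (linearly interpolated) rotation setpoint; the integer speed is
#' raised by `speed_step` when behind, lowered when ahead, held when equal,
#' and clamped. The rotation then advances by the (optionally disturbed)
#' motor rate times the tick length. The disturbance model is multiplicative
#' Gaussian rate noise of relative standard deviation `noise_sd` plus an
#' optional constant rate `bias` (degrees s^-1), applied only while the
#' motor runs; the effective rate is floored at 0 so delivery never
#' reverses.
#'
#' @param schedule a rotation schedule from [compile_schedule()].
#' @param config a [pump_config()]; its motor calibration drives the rates
#'   and its kinematics convert rotation to delivered volume.
#' @param settings a [controller_settings()].
#' @param noise_sd relative SD of the multiplicative rate noise (default
#'   0.02); set 0 for a deterministic run.
#' @param bias constant additive rate disturbance (degrees s^-1).
#' @param seed RNG seed; required whenever `noise_sd > 0`.
#' @return A `control_trace`: data.frame with columns `time_s`,
#'   `set_rotation_deg`, `actual_rotation_deg`, `speed_pct`,
#'   `delivered_volume_mL` (per syringe), with attributes `saturated`
#'   (setpoint slope exceeded full-speed capability at some tick) and
#'   `oversupply` (setpoint required less than the minimum-speed rate while
#'   stopping was disallowed).
#' @examples
#' cfg <- pump_config(standard_syringe("10 mL"), gear_train(2))
#' pr <- exponential_fedbatch_profile(fedbatch_spec(0.3, 50, 0.05, 0.35, 18), 2)
#' sched <- compile_schedule(pr, cfg)
#' tr <- simulate_tracking(sched, cfg, noise_sd = 0)
#' utils::tail(tr, 2)
#' @export
simulate_tracking <- function(schedule, config,
                              settings = controller_settings(),
                              noise_sd = 0.02, bias = 0, seed = NULL) {
  schedule <- as_rotation_schedule(schedule)
  if (!inherits(config, "pump_config"))
    pf_validation_stop("`config` must be a pump_config")
  if (!inherits(settings, "controller_settings"))
    pf_validation_stop("`settings` must be controller_settings")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0)
    pf_validation_stop("`noise_sd` must be a single non-negative number")
  if (noise_sd > 0 && is.null(seed))
    pf_validation_stop("a `seed` is required when the rate disturbance is stochastic (noise_sd > 0)")
  if (settings$speed_min < config$motor$dead_zone)
    pf_validation_stop("`speed_min` must not be below the motor dead zone")

  t_end <- max(schedule$time_s)
  dt <- settings$dt_control
  n <- max(1L, ceiling(t_end / dt))
  ticks <- seq_len(n) * dt
  ticks[n] <- min(ticks[n], t_end)
  setf <- approxfun(schedule$time_s, schedule$set_rotation_deg, rule = 2)

  eps <- if (noise_sd > 0) with_seed(seed, rnorm(n, 0, noise_sd)) else numeric(n)

  speed <- settings$speed_init
  actual <- 0
  speeds <- integer(n); actuals <- numeric(n)
  saturated <- FALSE; oversupply <- FALSE
  smin <- settings$speed_min; smax <- settings$speed_max
  step <- settings$speed_step
  gain <- config$motor$gain; dead <- config$motor$dead_zone

  prev_t <- 0
  for (i in seq_len(n)) {
    err <- actual - setf(prev_t)
    if (err < 0) {
      s2 <- speed + step
      if (s2 > smax) { s2 <- smax; saturated <- TRUE }
      if (s2 < smin) s2 <- smin  # re-engage from a stopped motor
    } else if (err > 0) {
      s2 <- speed - step
      if (s2 < smin) {
        if (settings$allow_stop) s2 <- 0L
        else { s2 <- smin; oversupply <- TRUE }
      }
    } else s2 <- speed
    speed <- as.integer(s2)
    rate <- if (speed == 0 || speed < dead) 0 else gain * speed
    if (rate > 0 || bias != 0) {
      rate <- rate * (1 + eps[i]) + bias
      if (rate < 0) rate <- 0
    }
    tick_len <- ticks[i] - prev_t
    actual <- actual + rate * tick_len
    speeds[i] <- speed; actuals[i] <- actual
    prev_t <- ticks[i]
  }

  out <- data.frame(
    time_s = c(0, ticks),
    set_rotation_deg = setf(c(0, ticks)),
    actual_rotation_deg = c(0, actuals),
    speed_pct = c(settings$speed_init, speeds),
    delivered_volume_mL = volume_for_rotation(c(0, actuals), config))
  attr(out, "saturated") <- saturated
  attr(out, "oversupply") <- oversupply
  attr(out, "config") <- config
  class(out) <- c("control_trace", "data.frame")
  out
}

#' @export
print.control_trace <- function(x, ...) {
  cat(sprintf("<control_trace> %d ticks over %g s; delivered %.4f mL; saturated: %s, oversupply: %s\n",
              nrow(x) - 1L, max(x$time_s), max(x$delivered_volume_mL),
              isTRUE(attr(x, "saturated")), isTRUE(attr(x, "oversupply"))))
  invisible(x)
}

#' Tracking-error statistics of a control trace
#'
#' Compares delivered volume with setpoint volume over the full horizon.
#' Because rotation and volume are proportional, relative volume errors
#' equal relative rotation errors; the maximum error is reported in
#' degrees. The setpoint is aligned to the trace's tick times by linear
#' interpolation of the schedule (actuals are never interpolated). Times
#' with zero setpoint volume are excluded from the relative errors.
#'
#' @param trace a `control_trace` from [simulate_tracking()].
#' @param schedule optionally, the original schedule to re-interpolate the
#'   setpoint from; by default the trace's stored setpoint column is used.
#' @return A list with `mean_signed_rel_pct`, `mean_abs_rel_pct` (per cent,
#'   on delivered vs setpoint volume) and `max_error_deg` (degrees).
#' @examples
#' cfg <- pump_config(standard_syringe("10 mL"), gear_train(2))
#' pr <- feed_profile(constant_segment(0.05, 600))
#' tr <- simulate_tracking(compile_schedule(pr, cfg), cfg, noise_sd = 0)
#' tracking_stats(tr)
#' @export
tracking_stats <- function(trace, schedule = NULL) {
  if (!inherits(trace, "control_trace"))
    pf_validation_stop("`trace` must be a control_trace")
  set <- if (is.null(schedule)) trace$set_rotation_deg
  else {
    schedule <- as_rotation_schedule(schedule)
    approx(schedule$time_s, schedule$set_rotation_deg, xout = trace$time_s,
           rule = 2)$y
  }
  act <- trace$actual_rotation_deg
  pos <- set > 0
  rel <- (act[pos] - set[pos]) / set[pos]
  list(mean_signed_rel_pct = 100 * mean(rel),
       mean_abs_rel_pct = 100 * mean(abs(rel)),
       max_error_deg = max(abs(act - set)))
}
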