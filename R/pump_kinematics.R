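# Pump kinematics: volume <-> piston travel <-> motor rotation, and the
# achievable flow envelope of a syringe/gear configuration.
#
# The core relation is
#   set_rotation(t) = V_F(t) * gdf * r_S * l_V        [degrees]
# where gdf is the gear-down factor (24 per worm-gear box), r_S the motor
# rotation per mm of actuator travel, and l_V the piston travel per mL for
# the mounted syringe type.

# Calibration anchors: the 50 mL-syringe / 0-gearbox reference flows at 100%
# and 5% motor speed (mL min^-1), measured with r_S = 150 deg/mm and
# l_V = 1.8 mm/mL. All other envelope cells scale from these two numbers.
.anchor_flow_full <- 210.3556
.anchor_flow_min <- 12.4212
.anchor_lv <- 1.8
.anchor_rs <- 150

#' Syringe geometry
#'
#' A syringe type is characterised by its travel-per-volume factor `l_V`
#' (mm of piston travel per mL dosed), its nominal capacity, and the usable
#' piston stroke. The linear actuator has a 40 mm stroke; to avoid end-stop
#' artefacts a dosing travel of 35 mm should not be exceeded, so 35 mm is
#' the default usable stroke.
#'
#' @param name label for the syringe type, e.g. `"10 mL"`.
#' @param l_V piston travel per volume dosed (mm mL^-1), > 0.
#' @param capacity nominal syringe volume (mL), > 0.
#' @param usable_stroke maximum piston travel during dosing (mm), in (0, 40].
#' @return An object of class `syringe_spec`.
#' @seealso [standard_syringe()] for the catalogue of stock syringe types.
#' @examples
#' syringe_spec("10 mL", l_V = 8, capacity = 10)
#' @export
syringe_spec <- function(name, l_V, capacity, usable_stroke = 35) {
  if (!is.numeric(l_V) || length(l_V) != 1 || !is.finite(l_V) || l_V <= 0)
    pf_validation_stop("`l_V` must be a single positive number (mm per mL)")
  if (!is.numeric(capacity) || length(capacity) != 1 || capacity <= 0)
    pf_validation_stop("`capacity` must be a single positive number (mL)")
  if (!is.numeric(usable_stroke) || length(usable_stroke) != 1 ||
      usable_stroke <= 0 || usable_stroke > 40)
    pf_validation_stop(
      "`usable_stroke` must lie in (0, 40] mm (actuator stroke is 40 mm)")
  structure(
    list(name = as.character(name), l_V = l_V, capacity = capacity,
         usable_stroke = usable_stroke),
    class = "syringe_spec")
}

#' @export
print.syringe_spec <- function(x, ...) {
  cat(sprintf("<syringe_spec> %s: l_V = %g mm/mL, capacity = %g mL, usable stroke = %g mm\n",
              x$name, x$l_V, x$capacity, x$usable_stroke))
  invisible(x)
}

#' Catalogue of stock syringe types
#'
#' Travel-per-volume factors for the syringe sizes the dosing unit was
#' characterised with: 1.8 mm/mL (50 mL), 5 mm/mL (20 mL), 8 mm/mL (10 mL)
#' and 57 mm/mL (1 mL). The 1 mL type is also available with `l_V` = 58,
#' the value implied by its printed maximum dosable volume of 0.6034 mL
#' (35/58); the two published values disagree slightly and neither is
#' silently corrected here.
#'
#' @param name one of `"50 mL"`, `"20 mL"`, `"10 mL"`, `"1 mL"`, `"1 mL (58)"`.
#' @return A [syringe_spec()].
#' @examples
#' standard_syringe("10 mL")
#' @export
standard_syringe <- function(name = c("50 mL", "20 mL", "10 mL", "1 mL", "1 mL (58)")) {
  name <- match.arg(name)
  switch(name,
    "50 mL" = syringe_spec("50 mL", l_V = 1.8, capacity = 50),
    "20 mL" = syringe_spec("20 mL", l_V = 5, capacity = 20),
    "10 mL" = syringe_spec("10 mL", l_V = 8, capacity = 10),
    "1 mL" = syringe_spec("1 mL", l_V = 57, capacity = 1),
    "1 mL (58)" = syringe_spec("1 mL (58)", l_V = 58, capacity = 1))
}

#' Gear-down factor of a worm-gear train
#'
#' Each gearbox stage (a worm gear driving a 24-tooth gearwheel) divides the
#' rotation speed by 24; `n` stages in a daisy chain give a gear-down factor
#' of 24^n.
#'
#' @param n_gearboxes number of gearbox stages (non-negative integer).
#' @return The dimensionless gear-down factor 24^n.
#' @examples
#' gear_down_factor(0) # 1
#' gear_down_factor(2) # 576
#' @export
gear_down_factor <- function(n_gearboxes) {
  if (!is.numeric(n_gearboxes) || length(n_gearboxes) != 1 ||
      is.na(n_gearboxes) || n_gearboxes != round(n_gearboxes) || n_gearboxes < 0)
    pf_validation_stop("`n_gearboxes` must be a single non-negative integer")
  24^n_gearboxes
}

#' Gear train configuration
#'
#' @param n_gearboxes number of gearbox stages mounted, 0, 1 or 2 (the unit
#'   accepts at most two in series).
#' @return An object of class `gear_train` with fields `n_gearboxes` and `gdf`.
#' @examples
#' gear_train(2)$gdf # 576
#' @export
gear_train <- function(n_gearboxes = 0) {
  if (!is.numeric(n_gearboxes) || length(n_gearboxes) != 1 ||
      is.na(n_gearboxes) || !n_gearboxes %in% 0:2)
    pf_validation_stop("`n_gearboxes` must be 0, 1 or 2")
  structure(
    list(n_gearboxes = as.integer(n_gearboxes),
         gdf = gear_down_factor(n_gearboxes)),
    class = "gear_train")
}

#' Motor calibration
#'
#' The motor is characterised twice, and the two calibrations serve
#' different purposes:
#' \itemize{
#'   \item `rate_at_full` / `rate_at_min`: measured rotation rates (degrees
#'     per minute) at 100% and 5% speed, back-computed from the reference
#'     flow cells of the 50 mL / 0-gearbox configuration. These anchor the
#'     flow envelope. Two independent anchors are kept because the measured
#'     5% rate is about 5.9% of the 100% rate, not 5% — the motor response
#'     is not perfectly proportional at its extremes.
#'   \item `gain`: the linear speed-to-rate factor (degrees s^-1 per
#'     %-speed) from a speed-sweep regression, used by the tracking
#'     controller to convert a commanded integer speed into a rotation rate.
#' }
#' Below `dead_zone` %-speed the motor response is non-linear and
#' unreliable; speeds below it are not used for dosing.
#'
#' @param rate_at_full rotation rate at 100% speed (degrees min^-1).
#' @param rate_at_min rotation rate at 5% speed (degrees min^-1).
#' @param gain linear speed-to-rate factor (degrees s^-1 per %-speed).
#' @param dead_zone minimum usable speed (%).
#' @return An object of class `motor_calibration`.
#' @examples
#' motor_calibration()
#' @export
motor_calibration <- function(rate_at_full = .anchor_flow_full * .anchor_lv * .anchor_rs,
                              rate_at_min = .anchor_flow_min * .anchor_lv * .anchor_rs,
                              gain = 8.5234,
                              dead_zone = 5) {
  if (!is.numeric(rate_at_full) || !is.numeric(rate_at_min) ||
      length(rate_at_full) != 1 || length(rate_at_min) != 1)
    pf_validation_stop("calibration rates must be single numbers (degrees per minute)")
  if (!(rate_at_full > rate_at_min && rate_at_min > 0))
    pf_validation_stop("calibration requires rate_at_full > rate_at_min > 0")
  if (!is.numeric(gain) || length(gain) != 1 || gain <= 0)
    pf_validation_stop("`gain` must be a single positive number")
  if (!is.numeric(dead_zone) || length(dead_zone) != 1 || dead_zone < 0 || dead_zone > 100)
    pf_validation_stop("`dead_zone` must lie in [0, 100] %")
  structure(
    list(rate_at_full = rate_at_full, rate_at_min = rate_at_min,
         gain = gain, dead_zone = dead_zone),
    class = "motor_calibration")
}

#' @export
print.motor_calibration <- function(x, ...) {
  cat(sprintf(paste0("<motor_calibration> %.1f deg/min @100%%, %.1f deg/min @5%%, ",
                     "gain %.4f deg/s/%%, dead zone %g%%\n"),
              x$rate_at_full, x$rate_at_min, x$gain, x$dead_zone))
  invisible(x)
}

#' Pump configuration
#'
#' Binds a syringe type, gear train, actuator pitch and motor calibration
#' into one dosing-channel configuration. `r_S` is the motor rotation
#' (degrees) per millimetre of linear-actuator travel: 90 deg/mm for the
#' prototype, drifting irreversibly to 150 deg/mm after exposure to counter
#' pressures above 1.5 bar (verify it periodically on real hardware). Up to
#' three syringes can be mounted in parallel on one actuator; all pistons
#' move identically, so `n_syringes` multiplies the delivered flow and the
#' total deliverable volume.
#'
#' @param syringe a [syringe_spec()].
#' @param gear a [gear_train()].
#' @param r_S rotation per piston travel (degrees mm^-1), > 0.
#' @param n_syringes syringes mounted in parallel (1-3).
#' @param motor a [motor_calibration()].
#' @return An object of class `pump_config`.
#' @examples
#' cfg <- pump_config(standard_syringe("10 mL"), gear_train(2))
#' rotation_for_volume(1, cfg) # 414720 degrees per mL
#' @export
pump_config <- function(syringe, gear = gear_train(0), r_S = 90,
                        n_syringes = 1, motor = motor_calibration()) {
  if (!inherits(syringe, "syringe_spec"))
    pf_validation_stop("`syringe` must be a syringe_spec")
  if (!inherits(gear, "gear_train"))
    pf_validation_stop("`gear` must be a gear_train")
  if (!inherits(motor, "motor_calibration"))
    pf_validation_stop("`motor` must be a motor_calibration")
  if (!is.numeric(r_S) || length(r_S) != 1 || r_S <= 0)
    pf_validation_stop("`r_S` must be a single positive number (degrees per mm)")
  if (!is.numeric(n_syringes) || length(n_syringes) != 1 ||
      !n_syringes %in% 1:3)
    pf_validation_stop("`n_syringes` must be 1, 2 or 3")
  structure(
    list(syringe = syringe, gear = gear, r_S = r_S,
         n_syringes = as.integer(n_syringes), motor = motor),
    class = "pump_config")
}

#' @export
print.pump_config <- function(x, ...) {
  cat(sprintf("<pump_config> %s syringe x%d, %d gearbox(es) (gdf %d), r_S = %g deg/mm\n",
              x$syringe$name, x$n_syringes, x$gear$n_gearboxes,
              as.integer(x$gear$gdf), x$r_S))
  invisible(x)
}

# degrees of rotation per mL dosed (per syringe)
degrees_per_ml <- function(config) {
  config$gear$gdf * config$r_S * config$syringe$l_V
}

#' Convert dosed volume to motor rotation and back
#'
#' `rotation_for_volume()` returns the cumulative motor rotation (degrees)
#' that doses `volume` mL from one syringe:
#' `rotation = volume * gdf * r_S * l_V`. `volume_for_rotation()` is the
#' exact inverse.
#'
#' @param volume volume dosed per syringe (mL), >= 0.
#' @param rotation cumulative motor rotation (degrees), >= 0.
#' @param config a [pump_config()].
#' @param check_stroke if `TRUE`, volumes beyond the stroke-limited maximum
#'   (`usable_stroke / l_V` per syringe) raise an error naming that maximum.
#' @return Rotation in degrees, or volume in mL. Vectorised over
#'   `volume`/`rotation`.
#' @examples
#' cfg <- pump_config(standard_syringe("10 mL"), gear_train(2))
#' rotation_for_volume(1, cfg)        # 414720
#' volume_for_rotation(414720, cfg)   # 1
#' @export
rotation_for_volume <- function(volume, config, check_stroke = TRUE) {
  if (!inherits(config, "pump_config"))
    pf_validation_stop("`config` must be a pump_config")
  if (!is.numeric(volume) || any(!is.finite(volume)) || any(volume < 0))
    pf_validation_stop("`volume` must be non-negative and finite (mL)")
  if (isTRUE(check_stroke)) {
    vmax <- config$syringe$usable_stroke / config$syringe$l_V
    if (any(volume > vmax * (1 + 1e-12)))
      pf_stop(sprintf(
        "volume %.4f mL exceeds the stroke-limited maximum of %.4f mL per syringe",
        max(volume), vmax), class = "pumpfeed_stroke_error")
  }
  volume * degrees_per_ml(config)
}

#' @rdname rotation_for_volume
#' @export
volume_for_rotation <- function(rotation, config) {
  if (!inherits(config, "pump_config"))
    pf_validation_stop("`config` must be a pump_config")
  if (!is.numeric(rotation) || any(!is.finite(rotation)) || any(rotation < 0))
    pf_validation_stop("`rotation` must be non-negative and finite (degrees)")
  rotation / degrees_per_ml(config)
}

#' Piston travel per degree of motor rotation
#'
#' Without gearing the actuator advances 1/r_S mm per degree (1.11e-2 mm at
#' r_S = 90); each gearbox stage divides this by 24.
#'
#' @param config a [pump_config()].
#' @return Piston displacement in mm per degree of motor rotation.
#' @examples
#' piston_travel_per_degree(pump_config(standard_syringe("10 mL"))) # 1/90
#' @export
piston_travel_per_degree <- function(config) {
  if (!inherits(config, "pump_config"))
    pf_validation_stop("`config` must be a pump_config")
  1 / (config$r_S * config$gear$gdf)
}

#' Achievable flow envelope of a pump configuration
#'
#' Scales the calibrated 100% and 5% rotation rates through the gear train
#' and syringe geometry: `v_dot = rate / (gdf * r_S * l_V)`. The maximum
#' dosable volume per syringe is `usable_stroke / l_V`. Per-syringe values
#' are the primary ones; when several syringes share the actuator the
#' aggregate flow/volume is `n_syringes` times larger.
#'
#' @param config a [pump_config()].
#' @return An object of class `flow_envelope` with fields `v_dot_max`,
#'   `v_dot_min` (mL min^-1 per syringe), `v_total_max` (mL per syringe),
#'   their `aggregate_*` counterparts, and `n_syringes`.
#' @examples
#' flow_envelope(pump_config(standard_syringe("10 mL"), r_S = 150))
#' @export
flow_envelope <- function(config) {
  if (!inherits(config, "pump_config"))
    pf_validation_stop("`config` must be a pump_config")
  m <- config$motor
  if (is.null(m$rate_at_full) || is.null(m$rate_at_min))
    pf_validation_stop("motor calibration anchors (rate_at_full, rate_at_min) are required")
  dpm <- degrees_per_ml(config)
  env <- list(
    v_dot_max = m$rate_at_full / dpm,
    v_dot_min = m$rate_at_min / dpm,
    v_total_max = config$syringe$usable_stroke / config$syringe$l_V,
    n_syringes = config$n_syringes)
  env$aggregate_v_dot_max <- env$v_dot_max * env$n_syringes
  env$aggregate_v_dot_min <- env$v_dot_min * env$n_syringes
  env$aggregate_v_total_max <- env$v_total_max * env$n_syringes
  if (env$v_total_max > config$syringe$capacity)
    warning("stroke-limited volume exceeds nominal syringe capacity; capacity governs",
            call. = FALSE)
  structure(env, class = "flow_envelope")
}

#' @export
print.flow_envelope <- function(x, digits = 4, ...) {
  cat(sprintf("<flow_envelope> per syringe (x%d mounted)\n", x$n_syringes))
  cat(sprintf("  max flow : %s mL/min (100%% speed)\n", format(round(x$v_dot_max, digits), nsmall = digits)))
  cat(sprintf("  min flow : %s mL/min (5%% speed)\n", format(round(x$v_dot_min, digits), nsmall = digits)))
  cat(sprintf("  max vol  : %s mL\n", format(round(x$v_total_max, digits), nsmall = digits)))
  invisible(x)
}

#' Specification table of the dosing unit
#'
#' Tabulates the flow envelope for every combination of stock syringe type
#' and gearbox count (0-2), in the layout of the unit's specification sheet:
#' maximum flow at 100% speed, minimum reliable flow at 5% speed, and
#' stroke-limited total volume per syringe. Values are computed from the
#' motor calibration anchors and rounded to `digits` decimals.
#'
#' @param motor a [motor_calibration()].
#' @param r_S rotation per travel used for the table (deg/mm); the
#'   published specification table uses 150.
#' @param syringes list of [syringe_spec()] objects (defaults to the stock
#'   catalogue).
#' @param gearboxes integer vector of gearbox counts.
#' @param digits decimals to round to; `NULL` for full precision.
#' @return A data.frame with columns `syringe`, `l_V`, `n_gearboxes`,
#'   `v_dot_max`, `v_dot_min`, `v_total_max`.
#' @examples
#' envelope_table()
#' @export
envelope_table <- function(motor = motor_calibration(), r_S = 150,
                           syringes = lapply(c("50 mL", "20 mL", "10 mL", "1 mL"),
                                             standard_syringe),
                           gearboxes = 0:2, digits = 4) {
  rows <- list()
  for (sy in syringes) {
    for (g in gearboxes) {
      cfg <- pump_config(sy, gear_train(g), r_S = r_S, motor = motor)
      env <- flow_envelope(cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        syringe = sy$name, l_V = sy$l_V, n_gearboxes = g,
        v_dot_max = env$v_dot_max, v_dot_min = env$v_dot_min,
        v_total_max = env$v_total_max)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(digits)) {
    for (cc in c("v_dot_max", "v_dot_min", "v_total_max"))
      out[[cc]] <- round(out[[cc]], digits)
  }
  out
}

#' Validate a rotation schedule against a pump configuration
#'
#' Checks every schedule interval's implied flow against the configuration's
#' flow envelope, and the total scheduled volume against the stroke-limited
#' maximum. Zero-flow intervals (pump idle) are allowed. By default a report
#' is returned; in strict mode the first violation raises an error.
#'
#' @param schedule a rotation schedule as produced by [compile_schedule()].
#' @param config a [pump_config()].
#' @param strict raise an error on the first violation instead of reporting.
#' @param tol relative tolerance on envelope bounds.
#' @return An object of class `schedule_validation`: a list with `ok`
#'   (logical), `flow_violations` (data.frame of offending intervals with
#'   the implied flow and the violated bound) and `volume_exceeded`
#'   (logical, with attributes giving the totals).
#' @export
validate_schedule <- function(schedule, config, strict = FALSE, tol = 1e-9) {
  if (!inherits(config, "pump_config"))
    pf_validation_stop("`config` must be a pump_config")
  schedule <- as_rotation_schedule(schedule)
  env <- flow_envelope(config)
  viol <- data.frame(t_start = numeric(0), t_end = numeric(0),
                     flow_mL_min = numeric(0), bound = character(0))
  n <- nrow(schedule)
  if (n >= 2) {
    dt_min <- diff(schedule$time_s) / 60
    dv <- diff(schedule$cumulative_volume_mL) / config$n_syringes
    fl <- dv / dt_min
    high <- fl > env$v_dot_max * (1 + tol)
    low <- fl > 0 & fl < env$v_dot_min * (1 - tol)
    bad <- which(high | low)
    if (length(bad))
      viol <- data.frame(
        t_start = schedule$time_s[bad], t_end = schedule$time_s[bad + 1L],
        flow_mL_min = fl[bad],
        bound = ifelse(high[bad], "above v_dot_max", "below v_dot_min"))
  }
  total <- if (n) max(schedule$cumulative_volume_mL) else 0
  vol_limit <- env$v_total_max * config$n_syringes
  vol_bad <- total > vol_limit * (1 + tol)
  if (strict && (nrow(viol) || vol_bad)) {
    msg <- if (nrow(viol))
      sprintf("schedule interval [%g, %g] s has implied flow %.6g mL/min (%s; envelope [%.4f, %.4f])",
              viol$t_start[1], viol$t_end[1], viol$flow_mL_min[1], viol$bound[1],
              env$v_dot_min, env$v_dot_max)
    else
      sprintf("scheduled volume %.4f mL exceeds the %.4f mL stroke limit", total, vol_limit)
    pf_stop(msg, class = "pumpfeed_envelope_error")
  }
  structure(
    list(ok = !nrow(viol) && !vol_bad,
         flow_violations = viol,
         volume_exceeded = structure(vol_bad, total_volume_mL = total,
                                     volume_limit_mL = vol_limit)),
    class = "schedule_validation")
}

#' @export
print.schedule_validation <- function(x, ...) {
  if (x$ok) {
    cat("<schedule_validation> OK: schedule within flow envelope and stroke limit\n")
  } else {
    cat(sprintf("<schedule_validation> %d flow violation(s); volume exceeded: %s\n",
                nrow(x$flow_violations), x$volume_exceeded))
    if (nrow(x$flow_violations)) print(utils::head(x$flow_violations, 10))
  }
  invisible(x)
}
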