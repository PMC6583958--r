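# Feed-profile design and compilation.
#
# A feed profile is an ordered list of flow segments (constant, linear ramp,
# exponential). Each segment has a closed-form integral, so a profile
# compiles to a cumulative-volume curve exactly: the volume at time t inside
# segment k is the sum of all completed segment volumes plus the partial
# integral of segment k. Rotation setpoints follow from the pump kinematics,
#   set_rotation(t) = V_F(t) * gdf * r_S * l_V.
#
# Times are in seconds, flows in mL min^-1; exponential segments carry their
# natural parameters b (mL) and a (h^-1), V_F(t) = b * (exp(a t) - 1).

#' Feed segments
#'
#' The building blocks of a feed profile. Flows are in mL min^-1, durations
#' in seconds; the exponential segment is parameterised by its volume
#' prefactor `b` (mL) and rate `a` (h^-1), giving flow
#' `a * b * exp(a * t)` (in mL h^-1; converted internally) and cumulative
#' volume `b * (exp(a * t) - 1)`.
#'
#' @param flow,from,to flows in mL min^-1 (non-negative).
#' @param duration segment duration in seconds, > 0.
#' @param b volume prefactor (mL), >= 0.
#' @param a exponential rate (h^-1); any real.
#' @return An object of class `feed_segment`.
#' @examples
#' constant_segment(0.5, duration = 600)
#' ramp_segment(0, 0.5, duration = 600)
#' exponential_segment(b = 0.119, a = 0.1, duration = 3600 * 10)
#' @export
constant_segment <- function(flow, duration) {
  new_segment("constant", duration, list(flow = check_flow(flow, "flow")))
}

#' @rdname constant_segment
#' @export
ramp_segment <- function(from, to, duration) {
  new_segment("ramp", duration,
              list(from = check_flow(from, "from"), to = check_flow(to, "to")))
}

#' @rdname constant_segment
#' @export
exponential_segment <- function(b, a, duration) {
  if (!is.numeric(b) || length(b) != 1 || !is.finite(b) || b < 0)
    pf_validation_stop("`b` must be a single non-negative number (mL)")
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a))
    pf_validation_stop("`a` must be a single finite number (h^-1)")
  new_segment("exponential", duration, list(b = b, a = a))
}

check_flow <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0)
    pf_validation_stop(sprintf("`%s` must be a single non-negative flow (mL/min)", what))
  x
}

new_segment <- function(kind, duration, params) {
  if (!is.numeric(duration) || length(duration) != 1 || !is.finite(duration) ||
      duration <= 0)
    pf_validation_stop("`duration` must be a single positive number of seconds")
  structure(list(kind = kind, duration = duration, params = params),
            class = "feed_segment")
}

#' @export
print.feed_segment <- function(x, ...) {
  p <- switch(x$kind,
    constant = sprintf("flow %g mL/min", x$params$flow),
    ramp = sprintf("%g -> %g mL/min", x$params$from, x$params$to),
    exponential = sprintf("b = %g mL, a = %g /h", x$params$b, x$params$a))
  cat(sprintf("<feed_segment> %s over %g s (%s)\n", x$kind, x$duration, p))
  invisible(x)
}

#' Instantaneous flow of a segment
#'
#' @param segment a [feed_segment()].
#' @param t time since segment start (s), within `[0, duration]`; vectorised.
#' @return Flow in mL min^-1.
#' @export
segment_flow <- function(segment, t) {
  check_segment_time(segment, t)
  switch(segment$kind,
    constant = rep_len(segment$params$flow, length(t)),
    ramp = with(segment$params, from + (to - from) * t / segment$duration),
    exponential = with(segment$params,
      per_hour_to_per_min(a * b * exp(a * seconds_to_hours(t)))))
}

#' Cumulative volume of a segment (closed form)
#'
#' Exact integral of the segment's flow from its start to local time `t`:
#' `Q * t` for constant flow, the trapezoid area for a ramp, and
#' `b * (exp(a*t) - 1)` for the exponential.
#'
#' @inheritParams segment_flow
#' @return Volume in mL.
#' @examples
#' segment_volume(constant_segment(0.5, 600), 600) # 5 mL
#' @export
segment_volume <- function(segment, t) {
  check_segment_time(segment, t)
  t_min <- t / 60
  switch(segment$kind,
    constant = segment$params$flow * t_min,
    ramp = with(segment$params,
      from * t_min + (to - from) * t^2 / (2 * segment$duration) / 60),
    exponential = with(segment$params, {
      if (a == 0) rep_len(0, length(t)) else b * (exp(a * seconds_to_hours(t)) - 1)
    }))
}

check_segment_time <- function(segment, t) {
  if (!inherits(segment, "feed_segment"))
    pf_validation_stop("`segment` must be a feed_segment")
  if (!is.numeric(t) || any(!is.finite(t)))
    pf_validation_stop("`t` must be finite numeric seconds")
  if (any(t < -1e-9) || any(t > segment$duration * (1 + 1e-12) + 1e-9))
    pf_stop(sprintf("t out of range [0, %g] s for this segment", segment$duration),
            class = "pumpfeed_domain_error")
  invisible(TRUE)
}

#' Feed profile: an ordered, contiguous sequence of segments on one channel
#'
#' @param segments a list of [feed_segment()] objects, played back to back
#'   starting at t = 0.
#' @param channel port label, one of `"A"`-`"D"`.
#' @return An object of class `feed_profile`.
#' @export
feed_profile <- function(segments = list(), channel = "A") {
  if (inherits(segments, "feed_segment")) segments <- list(segments)
  if (!is.list(segments) || !all(vapply(segments, inherits, TRUE, "feed_segment")))
    pf_validation_stop("`segments` must be a list of feed_segment objects")
  if (!is.character(channel) || length(channel) != 1 || !channel %in% LETTERS[1:4])
    pf_validation_stop("`channel` must be one of \"A\", \"B\", \"C\", \"D\"")
  structure(list(segments = segments, channel = channel), class = "feed_profile")
}

#' @export
print.feed_profile <- function(x, ...) {
  cat(sprintf("<feed_profile> channel %s, %d segment(s), duration %g s, total %.4f mL\n",
              x$channel, length(x$segments), profile_duration(x),
              profile_volume(x, profile_duration(x))))
  for (s in x$segments) print(s)
  invisible(x)
}

#' Duration, flow and cumulative volume of a profile
#'
#' `profile_duration()` is the total played time; `profile_flow()` and
#' `profile_volume()` evaluate the instantaneous flow and the exact
#' cumulative dosed volume at absolute time `t` (seconds from profile
#' start), summing completed segments in closed form.
#'
#' @param profile a [feed_profile()].
#' @param t absolute time from profile start (s); vectorised. Times beyond
#'   the profile's end hold the final volume (flow 0).
#' @return Seconds, mL min^-1, or mL respectively.
#' @export
profile_duration <- function(profile) {
  sum(vapply(profile$segments, function(s) s$duration, numeric(1)))
}

#' @rdname profile_duration
#' @export
profile_flow <- function(profile, t) {
  eval_profile(profile, t)$flow
}

#' @rdname profile_duration
#' @export
profile_volume <- function(profile, t) {
  eval_profile(profile, t)$volume
}

eval_profile <- function(profile, t) {
  if (!inherits(profile, "feed_profile"))
    pf_validation_stop("`profile` must be a feed_profile")
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < -1e-9))
    pf_validation_stop("`t` must be non-negative numeric seconds")
  segs <- profile$segments
  flow <- numeric(length(t)); vol <- numeric(length(t))
  if (!length(segs)) return(list(flow = flow, volume = vol))
  ends <- cumsum(vapply(segs, function(s) s$duration, numeric(1)))
  starts <- c(0, ends[-length(ends)])
  seg_vols <- vapply(seq_along(segs),
                     function(k) segment_volume(segs[[k]], segs[[k]]$duration),
                     numeric(1))
  cum_before <- c(0, cumsum(seg_vols))
  for (i in seq_along(t)) {
    ti <- min(max(t[i], 0), ends[length(ends)])
    k <- findInterval(ti, starts, rightmost.closed = FALSE)
    k <- max(1L, min(k, length(segs)))
    local_t <- ti - starts[k]
    vol[i] <- cum_before[k] + segment_volume(segs[[k]], local_t)
    flow[i] <- if (t[i] > ends[length(ends)] + 1e-9) 0 else segment_flow(segs[[k]], local_t)
  }
  list(flow = flow, volume = vol)
}

#' Fed-batch specification
#'
#' Parameters of the exponential substrate-feed law for setting a specific
#' growth rate: feeding `Vin(t) = mu_set * b * exp(mu_set * t)` with
#' `b = V_R * c_X0 / (Y_XS * c_S0)` supplies exactly the substrate a
#' culture growing at `mu_set` consumes, assuming immediate consumption and
#' negligible maintenance. `mu_set` outside [0.05, 0.5] h^-1 triggers a
#' plausibility warning; values outside (0, 2] are rejected.
#'
#' @param mu_set target specific growth rate (h^-1).
#' @param V_R culture volume (mL).
#' @param c_X0 biomass concentration at feed start (mg mL^-1).
#' @param Y_XS biomass yield on substrate (mg_CDW mg_S^-1).
#' @param c_S0 substrate concentration of the feed solution (mg mL^-1).
#' @return An object of class `fedbatch_spec`.
#' @examples
#' fedbatch_spec(mu_set = 0.1, V_R = 50, c_X0 = 0.03, Y_XS = 0.35, c_S0 = 36)
#' @export
fedbatch_spec <- function(mu_set, V_R, c_X0, Y_XS, c_S0) {
  for (nm in c("mu_set", "V_R", "c_X0", "Y_XS", "c_S0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      pf_validation_stop(sprintf("`%s` must be a single positive number", nm))
  }
  if (mu_set > 2)
    pf_validation_stop("`mu_set` above 2 h^-1 is outside the plausible range")
  if (mu_set < 0.05 || mu_set > 0.5)
    warning(sprintf("mu_set = %g h^-1 is outside the typical range [0.05, 0.5]", mu_set),
            call. = FALSE)
  structure(list(mu_set = mu_set, V_R = V_R, c_X0 = c_X0,
                 Y_XS = Y_XS, c_S0 = c_S0),
            class = "fedbatch_spec")
}

#' @export
print.fedbatch_spec <- function(x, ...) {
  cat(sprintf("<fedbatch_spec> mu_set %g /h, V_R %g mL, c_X0 %g mg/mL, Y_XS %g, c_S0 %g mg/mL (b = %.5f mL)\n",
              x$mu_set, x$V_R, x$c_X0, x$Y_XS, x$c_S0,
              x$V_R * x$c_X0 / (x$Y_XS * x$c_S0)))
  invisible(x)
}

#' Exponential fed-batch feed profile
#'
#' Builds the single-segment exponential profile implementing the feed law
#' `Vin(t) = mu_set * V_R * c_X0 / (Y_XS * c_S0) * exp(mu_set * t)`, whose
#' integral `V_F(t) = b * (exp(mu_set * t) - 1)` is the cumulative volume
#' to dose. A `mu_set` of exactly zero degenerates to a zero-flow constant
#' segment.
#'
#' @param spec a [fedbatch_spec()] (or `mu_set = 0` via the `mu_zero`
#'   escape hatch below).
#' @param t_end feed horizon (h), > 0.
#' @param channel port label.
#' @return A [feed_profile()] with one exponential segment.
#' @examples
#' sp <- fedbatch_spec(0.1, 50, 0.03, 0.35, 36)
#' pr <- exponential_fedbatch_profile(sp, t_end = 10)
#' profile_volume(pr, hours_to_seconds(10)) # 0.2046 mL
#' @export
exponential_fedbatch_profile <- function(spec, t_end, channel = "A") {
  if (!inherits(spec, "fedbatch_spec"))
    pf_validation_stop("`spec` must be a fedbatch_spec")
  if (!is.numeric(t_end) || length(t_end) != 1 || t_end <= 0)
    pf_validation_stop("`t_end` must be a single positive number of hours")
  b <- spec$V_R * spec$c_X0 / (spec$Y_XS * spec$c_S0)
  feed_profile(exponential_segment(b = b, a = spec$mu_set,
                                   duration = hours_to_seconds(t_end)),
               channel = channel)
}

#' Size an exponential feed to a target total volume
#'
#' For the feed function `V_F(t) = b * exp(a * t)` used in pump validation
#' runs, the prefactor that doses exactly `total_volume` over horizon `T`
#' is `b = total_volume * exp(-a * T)`. (In that validation convention the
#' dosed volume is `b * exp(a*t)` measured from the initial set point, so
#' `V_F(T) = total_volume` by construction.)
#'
#' @param total_volume volume to dose over the horizon (mL).
#' @param a exponential rate (h^-1).
#' @param T_h horizon (h), > 0.
#' @return The prefactor `b` in mL.
#' @examples
#' b_factor(4.375, a = 1, T_h = 5) # 0.0295 mL
#' @export
b_factor <- function(total_volume, a, T_h) {
  if (!is.numeric(total_volume) || length(total_volume) != 1 || total_volume < 0)
    pf_validation_stop("`total_volume` must be a single non-negative number (mL)")
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a))
    pf_validation_stop("`a` must be a single finite number (h^-1)")
  if (!is.numeric(T_h) || length(T_h) != 1 || T_h <= 0)
    pf_validation_stop("`T_h` must be a single positive number of hours")
  total_volume * exp(-a * T_h)
}

# Rotation schedules ------------------------------------------------------

as_rotation_schedule <- function(x) {
  if (inherits(x, "rotation_schedule")) return(x)
  need <- c("time_s", "set_rotation_deg", "cumulative_volume_mL", "flow_mL_min")
  if (is.data.frame(x) && all(need %in% names(x))) {
    if (is.unsorted(x$time_s, strictly = TRUE))
      pf_validation_stop("schedule times must be strictly increasing")
    class(x) <- c("rotation_schedule", "data.frame")
    return(x)
  }
  pf_validation_stop(
    "expected a rotation_schedule (columns time_s, set_rotation_deg, cumulative_volume_mL, flow_mL_min)")
}

#' Compile a feed profile into a rotation schedule
#'
#' Evaluates the profile's closed-form cumulative volume on a regular time
#' grid (which always includes every segment boundary exactly) and converts
#' it to cumulative motor-rotation setpoints via the pump kinematics. When
#' several syringes share the actuator (`n_syringes > 1`), the profile's
#' flow is the channel's aggregate stream and each syringe delivers
#' `1/n_syringes` of it, so the rotation corresponds to the per-syringe
#' volume.
#'
#' The default 30 s grid matches the recalculation interval used for
#' feeding profiles; purification programs use a much finer grid (see
#' [purification_program()]).
#'
#' @param profile a [feed_profile()].
#' @param config a [pump_config()].
#' @param dt grid spacing (s), > 0.
#' @param check_stroke error if the per-syringe volume exceeds the stroke
#'   limit.
#' @return A `rotation_schedule`: a data.frame with columns `time_s`,
#'   `set_rotation_deg`, `cumulative_volume_mL` (channel aggregate) and
#'   `flow_mL_min` (channel aggregate), with the config attached as
#'   attribute `config`.
#' @examples
#' cfg <- pump_config(standard_syringe("10 mL"), gear_train(2))
#' pr <- exponential_fedbatch_profile(fedbatch_spec(0.1, 50, 0.03, 0.35, 36), 10)
#' sched <- compile_schedule(pr, cfg)
#' utils::tail(sched, 1)
#' @export
compile_schedule <- function(profile, config, dt = 30, check_stroke = TRUE) {
  if (!inherits(profile, "feed_profile"))
    pf_validation_stop("`profile` must be a feed_profile")
  if (!inherits(config, "pump_config"))
    pf_validation_stop("`config` must be a pump_config")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    pf_validation_stop("`dt` must be a single positive number of seconds")
  dur <- profile_duration(profile)
  if (dur == 0) {
    out <- data.frame(time_s = 0, set_rotation_deg = 0,
                      cumulative_volume_mL = 0, flow_mL_min = 0)
  } else {
    ends <- cumsum(vapply(profile$segments, function(s) s$duration, numeric(1)))
    grid <- sort(unique(c(seq(0, dur, by = dt), ends, dur)))
    ev <- eval_profile(profile, grid)
    per_syringe <- ev$volume / config$n_syringes
    rot <- rotation_for_volume(per_syringe, config, check_stroke = check_stroke)
    out <- data.frame(time_s = grid, set_rotation_deg = rot,
                      cumulative_volume_mL = ev$volume, flow_mL_min = ev$flow)
  }
  attr(out, "config") <- config
  attr(out, "channel") <- profile$channel
  class(out) <- c("rotation_schedule", "data.frame")
  out
}

#' @export
print.rotation_schedule <- function(x, ...) {
  cat(sprintf("<rotation_schedule> %d rows over %g s; final volume %.4f mL, final setpoint %.1f deg\n",
              nrow(x), max(x$time_s), max(x$cumulative_volume_mL),
              max(x$set_rotation_deg)))
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' Complementary ramp pair for gradient elution
#'
#' Two simultaneous ramp profiles whose flows always sum to `total_flow`:
#' one channel ramps from `total_flow` down to zero while the other ramps
#' up from zero, producing a linear concentration gradient at a constant
#' column inflow (the low-concentration buffer decreasing while the
#' high-concentration buffer increases).
#'
#' @param total_flow constant combined flow (mL min^-1), > 0.
#' @param T gradient duration (s), > 0.
#' @param channels labels for the (down, up) channels.
#' @return A named list of two [feed_profile()] objects, `down` and `up`.
#' @examples
#' gp <- gradient_pair(0.5, T = 1200)
#' profile_flow(gp$down, 600) + profile_flow(gp$up, 600) # 0.5
#' @export
gradient_pair <- function(total_flow, T, channels = c("C", "D")) {
  if (!is.numeric(total_flow) || length(total_flow) != 1 || total_flow <= 0)
    pf_validation_stop("`total_flow` must be a single positive flow (mL/min)")
  if (!is.numeric(T) || length(T) != 1 || T <= 0)
    pf_validation_stop("`T` must be a single positive duration (s)")
  list(
    down = feed_profile(ramp_segment(total_flow, 0, T), channel = channels[1]),
    up = feed_profile(ramp_segment(0, total_flow, T), channel = channels[2]))
}

#' Four-channel His-tag purification program
#'
#' The standard IMAC sequence expressed as four synchronised channel
#' profiles at a constant column inflow: load 4 column volumes (CV) of
#' lysate from port A, wash 5 CV from port B, elute over a 10 CV linear
#' gradient formed by ramping port C (low-imidazole wash buffer) down and
#' port D (high-imidazole elution buffer) up, then rinse 2 CV of elution
#' buffer from port D. Profiles carry the channel's stream flow; when a
#' port drives two syringes in parallel the per-syringe flow is halved at
#' compile time via the config's `n_syringes`.
#'
#' Inactive phases are padded with zero-flow segments so that all four
#' profiles share the common timeline and the summed column inflow is
#' `flow` throughout.
#'
#' @param column_volume the column bed volume (mL), > 0.
#' @param flow constant column inflow (mL min^-1), > 0.
#' @param cv_load,cv_wash,cv_gradient,cv_rinse phase lengths in CV.
#' @return A named list of four [feed_profile()] objects (`A`-`D`) plus a
#'   `phases` data.frame (phase, channel, start_s, end_s, volume_mL).
#' @examples
#' pp <- purification_program(column_volume = 1, flow = 0.5)
#' pp$phases
#' @export
purification_program <- function(column_volume, flow,
                                 cv_load = 4, cv_wash = 5,
                                 cv_gradient = 10, cv_rinse = 2) {
  if (!is.numeric(column_volume) || length(column_volume) != 1 || column_volume <= 0)
    pf_validation_stop("`column_volume` must be a single positive number (mL)")
  if (!is.numeric(flow) || length(flow) != 1 || flow <= 0)
    pf_validation_stop("`flow` must be a single positive flow (mL/min)")
  cv <- c(load = cv_load, wash = cv_wash, gradient = cv_gradient, rinse = cv_rinse)
  dur <- cv * column_volume / flow * 60  # seconds per phase
  ends <- cumsum(dur); starts <- c(0, ends[-4])
  pad <- function(d) if (d > 0) list(constant_segment(0, d)) else list()

  prof_A <- feed_profile(c(list(constant_segment(flow, dur[1])),
                           pad(sum(dur[2:4]))), channel = "A")
  prof_B <- feed_profile(c(pad(dur[1]),
                           list(constant_segment(flow, dur[2])),
                           pad(sum(dur[3:4]))), channel = "B")
  prof_C <- feed_profile(c(pad(sum(dur[1:2])),
                           list(ramp_segment(flow, 0, dur[3])),
                           pad(dur[4])), channel = "C")
  prof_D <- feed_profile(c(pad(sum(dur[1:2])),
                           list(ramp_segment(0, flow, dur[3]),
                                constant_segment(flow, dur[4]))), channel = "D")
  phases <- data.frame(
    phase = c("load", "wash", "gradient down", "gradient up", "rinse"),
    channel = c("A", "B", "C", "D", "D"),
    start_s = c(starts[1:3], starts[3], starts[4]),
    end_s = c(ends[1:3], ends[3], ends[4]),
    volume_mL = c(cv[1:2] * column_volume,
                  cv[3] * column_volume / 2, cv[3] * column_volume / 2,
                  cv[4] * column_volume))
  list(A = prof_A, B = prof_B, C = prof_C, D = prof_D, phases = phases)
}
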