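# File formats.
#
# Configuration documents are YAML with fixed section vocabularies; unknown
# keys are rejected with the file, section and key named, so typos never
# silently fall back to defaults. Tabular outputs are plain CSV with a
# header row, dot decimals, UTF-8 and LF line endings.

check_keys <- function(x, allowed, file, section) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    pf_validation_stop(sprintf("%s: unknown key(s) in `%s`: %s (allowed: %s)",
                               file, section, paste(extra, collapse = ", "),
                               paste(allowed, collapse = ", ")))
  invisible(TRUE)
}

pump_config_from_list <- function(x, file = "<config>") {
  check_keys(x, c("syringe", "gear", "r_S", "n_syringes", "motor"), file, "pump")
  if (is.null(x$syringe))
    pf_validation_stop(file, ": `pump` needs a `syringe` entry")
  sy <- if (is.character(x$syringe) && length(x$syringe) == 1)
    standard_syringe(x$syringe)
  else {
    check_keys(x$syringe, c("name", "l_V", "capacity", "usable_stroke"),
               file, "pump/syringe")
    do.call(syringe_spec, x$syringe)
  }
  gear <- if (is.null(x$gear)) gear_train(0) else {
    check_keys(x$gear, "n_gearboxes", file, "pump/gear")
    gear_train(x$gear$n_gearboxes)
  }
  motor <- if (is.null(x$motor)) motor_calibration() else {
    check_keys(x$motor, c("rate_at_full", "rate_at_min", "gain", "dead_zone"),
               file, "pump/motor")
    do.call(motor_calibration, x$motor)
  }
  pump_config(sy, gear,
              r_S = if (is.null(x$r_S)) 90 else x$r_S,
              n_syringes = if (is.null(x$n_syringes)) 1 else x$n_syringes,
              motor = motor)
}

#' Read and write pump configurations as YAML
#'
#' The document has a single `pump` section with entries `syringe` (either
#' a stock-syringe name such as `"10 mL"` or a mapping with `name`, `l_V`,
#' `capacity`, `usable_stroke`), `gear` (`n_gearboxes`), `r_S`,
#' `n_syringes` and `motor` (`rate_at_full`, `rate_at_min`, `gain`,
#' `dead_zone`). Unknown keys are rejected, naming the file, section and
#' key.
#'
#' @param path file path.
#' @param config a [pump_config()].
#' @return `read_pump_config()` returns a [pump_config()];
#'   `write_pump_config()` returns `path` invisibly.
#' @export
read_pump_config <- function(path) {
  doc <- yaml::read_yaml(path)
  check_keys(doc, "pump", path, "<top level>")
  if (is.null(doc$pump))
    pf_validation_stop(path, ": missing `pump` section")
  pump_config_from_list(doc$pump, file = path)
}

#' @rdname read_pump_config
#' @export
write_pump_config <- function(config, path) {
  if (!inherits(config, "pump_config"))
    pf_validation_stop("`config` must be a pump_config")
  doc <- list(pump = list(
    syringe = config$syringe[c("name", "l_V", "capacity", "usable_stroke")],
    gear = list(n_gearboxes = config$gear$n_gearboxes),
    r_S = config$r_S,
    n_syringes = config$n_syringes,
    motor = config$motor[c("rate_at_full", "rate_at_min", "gain", "dead_zone")]))
  yaml::write_yaml(doc, path)
  invisible(path)
}

segment_from_list <- function(x, file) {
  if (is.null(x$kind))
    pf_validation_stop(file, ": each segment needs a `kind`")
  switch(x$kind,
    constant = {
      check_keys(x, c("kind", "flow", "duration"), file, "segment")
      constant_segment(x$flow, x$duration)
    },
    ramp = {
      check_keys(x, c("kind", "from", "to", "duration"), file, "segment")
      ramp_segment(x$from, x$to, x$duration)
    },
    exponential = {
      check_keys(x, c("kind", "b", "a", "duration"), file, "segment")
      exponential_segment(x$b, x$a, x$duration)
    },
    pf_validation_stop(file, ": unknown segment kind `", x$kind,
                       "` (constant, ramp, exponential)"))
}

#' Read and write feed profiles as YAML
#'
#' Two document forms are accepted: a `profile` section (`channel` plus a
#' `segments` list, each segment a mapping with `kind` constant / ramp /
#' exponential and its parameters), or a `fedbatch` section (`mu_set`,
#' `V_R`, `c_X0`, `Y_XS`, `c_S0`, `t_end_h`, optional `channel`) which is
#' expanded into the single-segment exponential feed profile.
#'
#' @param path file path.
#' @param profile a [feed_profile()].
#' @return `read_feed_profile()` returns a [feed_profile()];
#'   `write_feed_profile()` returns `path` invisibly.
#' @export
read_feed_profile <- function(path) {
  doc <- yaml::read_yaml(path)
  check_keys(doc, c("profile", "fedbatch"), path, "<top level>")
  if (!is.null(doc$fedbatch)) {
    fb <- doc$fedbatch
    check_keys(fb, c("mu_set", "V_R", "c_X0", "Y_XS", "c_S0", "t_end_h", "channel"),
               path, "fedbatch")
    spec <- fedbatch_spec(fb$mu_set, fb$V_R, fb$c_X0, fb$Y_XS, fb$c_S0)
    return(exponential_fedbatch_profile(
      spec, fb$t_end_h,
      channel = if (is.null(fb$channel)) "A" else fb$channel))
  }
  if (is.null(doc$profile))
    pf_validation_stop(path, ": need a `profile` or `fedbatch` section")
  pr <- doc$profile
  check_keys(pr, c("channel", "segments"), path, "profile")
  segs <- lapply(pr$segments, segment_from_list, file = path)
  feed_profile(segs, channel = if (is.null(pr$channel)) "A" else pr$channel)
}

#' @rdname read_feed_profile
#' @export
write_feed_profile <- function(profile, path) {
  if (!inherits(profile, "feed_profile"))
    pf_validation_stop("`profile` must be a feed_profile")
  segs <- lapply(profile$segments, function(s)
    c(list(kind = s$kind), s$params, list(duration = s$duration)))
  yaml::write_yaml(list(profile = list(channel = profile$channel,
                                       segments = segs)), path)
  invisible(path)
}

#' Read and write rotation schedules and control traces as CSV
#'
#' Schedules use the columns `time_s`, `set_rotation_deg`,
#' `cumulative_volume_mL`, `flow_mL_min`; traces add
#' `actual_rotation_deg` and `speed_pct`. Round-tripping a schedule
#' preserves it exactly at the printed precision (full double precision is
#' written).
#'
#' @param schedule,trace the object to write.
#' @param path file path.
#' @return Readers return the object; writers return `path` invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  schedule <- as_rotation_schedule(schedule)
  write.csv(as.data.frame(schedule), path, row.names = FALSE,
            quote = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  as_rotation_schedule(read.csv(path, fileEncoding = "UTF-8"))
}

#' @rdname write_schedule_csv
#' @export
write_trace_csv <- function(trace, path) {
  if (!inherits(trace, "control_trace"))
    pf_validation_stop("`trace` must be a control_trace")
  write.csv(as.data.frame(trace), path, row.names = FALSE,
            quote = FALSE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a combined run configuration
#'
#' A run configuration bundles the sections `pump`, `profile` or
#' `fedbatch`, `bioprocess`, `controller`, `synth`, plus a global `seed`
#' and an `outdir`, in one YAML document. Each present section is parsed
#' with the same strict key checking as the single-purpose readers; the
#' fully resolved configuration is echoed back in the returned object for
#' reproducibility.
#'
#' @param path file path.
#' @return A list of class `run_config` with any of `pump` (a
#'   [pump_config()]), `profile` (a [feed_profile()]), `bioprocess` (a
#'   [bioprocess_params()]), `controller` (a [controller_settings()]),
#'   `synth` (a raw list), `seed`, `outdir`.
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  allowed <- c("pump", "profile", "fedbatch", "bioprocess", "controller",
               "synth", "seed", "outdir")
  check_keys(doc, allowed, path, "<top level>")
  out <- list()
  if (!is.null(doc$pump)) out$pump <- pump_config_from_list(doc$pump, path)
  if (!is.null(doc$profile) || !is.null(doc$fedbatch)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp), add = TRUE)
    yaml::write_yaml(doc[intersect(names(doc), c("profile", "fedbatch"))], tmp)
    out$profile <- read_feed_profile(tmp)
  }
  if (!is.null(doc$bioprocess)) {
    check_keys(doc$bioprocess,
               c("Y_XS", "q_S_max", "K_S", "c_S0", "ngam", "substrate_per_atp",
                 "V_R", "c_X0"),
               path, "bioprocess")
    bp <- doc$bioprocess
    out$initial <- culture_state(V_R = if (is.null(bp$V_R)) 50 else bp$V_R,
                                 c_X = if (is.null(bp$c_X0)) 0.04 else bp$c_X0)
    out$bioprocess <- do.call(bioprocess_params,
                              bp[setdiff(names(bp), c("V_R", "c_X0"))])
  }
  if (!is.null(doc$controller)) {
    check_keys(doc$controller,
               c("dt_control", "speed_step", "speed_init", "speed_min",
                 "speed_max", "allow_stop"), path, "controller")
    out$controller <- do.call(controller_settings, doc$controller)
  }
  if (!is.null(doc$synth)) out$synth <- doc$synth
  out$seed <- doc$seed
  out$outdir <- doc$outdir
  structure(out, class = "run_config")
}
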