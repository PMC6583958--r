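# Synthetic measurement data.
#
# Emulates the measurement modalities around the dosing unit — optical
# density sampling of a growing culture, gravimetric dosing traces on an
# analytical balance, mu-q_S yield datasets, droplet-diameter samples — so
# that every analysis path can be exercised with known ground truth. Noise
# structures (lognormal for OD, additive for the balance) are this
# package's modelling choices; every generator is deterministic given its
# seed and touches no global RNG state.

#' Synthetic optical-density series of an exponentially growing culture
#'
#' OD proportional to `c_X0 * exp(mu * t)` sampled on a regular grid, with
#' multiplicative lognormal noise: `OD_i = k * c_X0 * exp(mu t_i) *
#' exp(e_i)`, `e_i ~ N(0, sigma_rel^2)`. The default 1.5 h cadence matches
#' routine plate-reader sampling of shaking-flask cultures.
#'
#' @param mu true specific growth rate (h^-1); may be 0 for a flat series.
#' @param c_X0 initial biomass concentration (mg mL^-1), > 0.
#' @param t_end series end (h), > 0.
#' @param dt sampling interval (h), > 0.
#' @param sigma_rel relative noise SD (log scale), >= 0.
#' @param seed RNG seed (required).
#' @param od_per_mg proportionality of OD to biomass concentration.
#' @return A data.frame with columns `t_h` and `od`.
#' @examples
#' s <- synth_od_series(0.3, 0.05, t_end = 12, sigma_rel = 0.03, seed = 1)
#' estimate_growth_rate(s$t_h, s$od)$mu_hat
#' @export
synth_od_series <- function(mu, c_X0, t_end, dt = 1.5, sigma_rel = 0.03,
                            seed, od_per_mg = 2.5) {
  if (!is.numeric(mu) || length(mu) != 1 || !is.finite(mu) || mu < 0)
    pf_validation_stop("`mu` must be a single non-negative number (h^-1)")
  if (!is.numeric(c_X0) || length(c_X0) != 1 || c_X0 <= 0)
    pf_validation_stop("`c_X0` must be a single positive number (mg/mL)")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    pf_validation_stop("`dt` must be a single positive number of hours")
  if (!is.numeric(t_end) || length(t_end) != 1 || t_end <= 0)
    pf_validation_stop("`t_end` must be a single positive number of hours")
  if (!is.numeric(sigma_rel) || length(sigma_rel) != 1 || sigma_rel < 0)
    pf_validation_stop("`sigma_rel` must be a single non-negative number")
  t <- seq(0, t_end, by = dt)
  clean <- od_per_mg * c_X0 * exp(mu * t)
  noise <- if (sigma_rel > 0)
    with_seed(seed, exp(rnorm(length(t), 0, sigma_rel))) else {
    with_seed(seed, NULL); rep_len(1, length(t))
  }
  data.frame(t_h = t, od = clean * noise)
}

#' Synthetic mu-q_S dataset with a known yield
#'
#' Growth rates generated as `mu_i = yield * q_S_i * (1 + e_i)`,
#' `e_i ~ N(0, sigma_rel^2)`, the data structure behind origin-constrained
#' yield fitting.
#'
#' @param yield true biomass yield (mg_CDW mg_S^-1), > 0.
#' @param q_s_values substrate uptake rates to evaluate at (non-empty,
#'   positive).
#' @param sigma_rel relative noise SD, >= 0.
#' @param seed RNG seed (required).
#' @param strain strain label for the records.
#' @return A [mu_qs_dataset()].
#' @examples
#' d <- synth_mu_qs(0.35, seq(0.2, 1.4, length.out = 12), 0.05, seed = 7)
#' fit_yield(d)$yield
#' @export
synth_mu_qs <- function(yield, q_s_values, sigma_rel = 0.05, seed,
                        strain = "wildtype") {
  if (!is.numeric(yield) || length(yield) != 1 || yield <= 0)
    pf_validation_stop("`yield` must be a single positive number")
  if (!is.numeric(q_s_values) || length(q_s_values) == 0 ||
      any(!is.finite(q_s_values)) || any(q_s_values <= 0))
    pf_validation_stop("`q_s_values` must be a non-empty vector of positive rates")
  if (!is.numeric(sigma_rel) || length(sigma_rel) != 1 || sigma_rel < 0)
    pf_validation_stop("`sigma_rel` must be a single non-negative number")
  eps <- if (sigma_rel > 0)
    with_seed(seed, rnorm(length(q_s_values), 0, sigma_rel)) else {
    with_seed(seed, NULL); numeric(length(q_s_values))
  }
  mu <- pmax(yield * q_s_values * (1 + eps), 0)
  mu_qs_dataset(q_S = q_s_values, mu = mu, strain = strain)
}

#' Synthetic gravimetric dosing trace
#'
#' Emulates weighing dosed water on an analytical balance: cumulative mass
#' is the scheduled volume times 0.997 mg uL^-1 (water at room
#' temperature), plus additive Gaussian balance noise, minus a linear
#' evaporation drift.
#'
#' @param schedule a rotation schedule from [compile_schedule()]; its
#'   cumulative volume column is the ground truth.
#' @param scale_sd balance noise SD (mg), >= 0.
#' @param evaporation_rate evaporative loss (mg h^-1), >= 0.
#' @param seed RNG seed (required).
#' @return A data.frame with columns `t_s` and `mass_mg`.
#' @export
synth_gravimetric_trace <- function(schedule, scale_sd = 0.05,
                                    evaporation_rate = 0, seed) {
  schedule <- as_rotation_schedule(schedule)
  if (!is.numeric(scale_sd) || length(scale_sd) != 1 || scale_sd < 0)
    pf_validation_stop("`scale_sd` must be a single non-negative number (mg)")
  if (!is.numeric(evaporation_rate) || length(evaporation_rate) != 1 ||
      !is.finite(evaporation_rate) || evaporation_rate < 0)
    pf_validation_stop("`evaporation_rate` must be a single non-negative number (mg/h)")
  n <- nrow(schedule)
  noise <- if (scale_sd > 0) with_seed(seed, rnorm(n, 0, scale_sd)) else {
    with_seed(seed, NULL); numeric(n)
  }
  mass <- schedule$cumulative_volume_mL * 997 + noise -
    evaporation_rate * seconds_to_hours(schedule$time_s)
  data.frame(t_s = schedule$time_s, mass_mg = mass)
}

#' Synthetic droplet-diameter sample
#'
#' Truncated-at-zero normal sample of bead diameters, as produced when a
#' constant-flow dripping process is sized under a microscope.
#'
#' @param mean,sd distribution parameters (mm); `mean` > 0, `sd` >= 0.
#' @param n sample size, >= 1.
#' @param seed RNG seed (required).
#' @return A numeric vector of diameters (mm).
#' @examples
#' d <- synth_bead_diameters(2.92, 0.17, 200, seed = 3)
#' bead_size_stats(d)$mean
#' @export
synth_bead_diameters <- function(mean, sd, n, seed) {
  if (!is.numeric(mean) || length(mean) != 1 || mean <= 0)
    pf_validation_stop("`mean` must be a single positive number (mm)")
  if (!is.numeric(sd) || length(sd) != 1 || sd < 0)
    pf_validation_stop("`sd` must be a single non-negative number (mm)")
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    pf_validation_stop("`n` must be a positive integer")
  if (sd == 0) { with_seed(seed, NULL); return(rep_len(mean, n)) }
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- rnorm(2 * n, mean, sd)
      out <- c(out, draw[draw > 0])
    }
    out[seq_len(n)]
  })
}
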