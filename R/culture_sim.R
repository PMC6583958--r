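# Fed-batch culture simulation.
#
# Substrate mass balance of a fed vessel:
#   d(V c_S)/dt = Vin * c_S0 - c_X * q_S * V
# closed with Monod uptake q_S = q_S_max * c_S / (K_S + c_S) and the
# standard biomass balance d(V c_X)/dt = mu c_X V, mu = Y_XS * q_S.
# The feed law targets the immediate-consumption limit (c_S << c_S0); a
# small half-saturation constant makes that limit numerically well-posed
# while recovering c_X -> c_X0 * exp(mu_set t) as K_S -> 0.

#' Bioprocess kinetic parameters
#'
#' Defaults describe glucose-limited *E. coli* in minimal medium:
#' yield `Y_XS` 0.35 mg_CDW mg_S^-1, maximum uptake `q_S_max` 1.8
#' mg_S mg_CDW^-1 h^-1 (supporting mu up to ~0.63 h^-1), and a small
#' half-saturation `K_S` so that substrate is consumed essentially
#' immediately. Non-growth-associated maintenance (`ngam`, in
#' mmol_ATP g_CDW^-1 h^-1; literature value 8.39) is negligible at these
#' rates and defaults to 0; when enabled it is converted to a substrate
#' drain via `substrate_per_atp` (mg substrate per mmol ATP; the default
#' 0.0103 corresponds to aerobic glucose catabolism at ~17.5 mol ATP per
#' mol glucose).
#'
#' @param Y_XS biomass yield (mg_CDW mg_S^-1).
#' @param q_S_max maximum specific substrate uptake (mg_S mg_CDW^-1 h^-1).
#' @param K_S Monod half-saturation (mg mL^-1).
#' @param c_S0 substrate concentration of the feed (mg mL^-1).
#' @param ngam non-growth-associated maintenance (mmol_ATP g_CDW^-1 h^-1).
#' @param substrate_per_atp conversion, mg substrate per mmol ATP.
#' @return An object of class `bioprocess_params`.
#' @examples
#' bioprocess_params(c_S0 = 36)
#' @export
bioprocess_params <- function(Y_XS = 0.35, q_S_max = 1.8, K_S = 0.005,
                              c_S0, ngam = 0, substrate_per_atp = 0.0103) {
  for (nm in c("Y_XS", "q_S_max", "K_S", "c_S0", "ngam", "substrate_per_atp")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      pf_validation_stop(sprintf("`%s` must be a single non-negative number", nm))
  }
  if (c_S0 <= 0) pf_validation_stop("`c_S0` must be positive (mg/mL)")
  if (Y_XS > 1)
    warning("Y_XS above 1 mg_CDW/mg_S is implausible for a carbon substrate",
            call. = FALSE)
  structure(list(Y_XS = Y_XS, q_S_max = q_S_max, K_S = K_S, c_S0 = c_S0,
                 ngam = ngam, substrate_per_atp = substrate_per_atp),
            class = "bioprocess_params")
}

#' Culture state
#'
#' @param t time (h), >= 0.
#' @param V_R culture volume (mL), > 0.
#' @param c_X biomass concentration (mg mL^-1), >= 0.
#' @param c_S dissolved substrate concentration (mg mL^-1), >= 0.
#' @return An object of class `culture_state`.
#' @examples
#' culture_state(V_R = 50, c_X = 0.03)
#' @export
culture_state <- function(t = 0, V_R, c_X, c_S = 0) {
  for (nm in c("t", "V_R", "c_X", "c_S")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      pf_validation_stop(sprintf("`%s` must be a single non-negative number", nm))
  }
  if (V_R <= 0) pf_validation_stop("`V_R` must be positive (mL)")
  structure(list(t = t, V_R = V_R, c_X = c_X, c_S = c_S),
            class = "culture_state")
}

#' Simulate a fed culture under a given feed-flow function
#'
#' Integrates the coupled substrate and biomass balances with adaptive
#' stepping (lsoda). By default the culture volume is held constant (the
#' dosed volume being of the same order as sampling withdrawals); with
#' `track_volume = TRUE` the vessel volume grows by the feed (dV/dt = Vin).
#' Book-keeping states for dosed volume and consumed substrate are carried
#' along so that mass conservation can be checked on the output.
#'
#' @param initial a [culture_state()] at t = 0.
#' @param params a [bioprocess_params()].
#' @param feed_flow a function of time (h) returning the feed flow in
#'   mL h^-1 (see [feed_flow_from_profile()] and [feed_flow_from_trace()]),
#'   or a single number for a constant flow.
#' @param t_end simulation horizon (h), > 0.
#' @param dt_out output grid spacing (h).
#' @param track_volume grow the vessel volume by the feed.
#' @param atol,rtol solver tolerances (absolute tolerance on
#'   concentration-scale states defaults to 1e-10).
#' @return A data.frame of class `culture_trajectory` with columns `t_h`,
#'   `V_mL`, `cX_mg_per_mL`, `cS_mg_per_mL`, `mu_inst_per_h`,
#'   `qS_mg_per_mg_h`, `dosed_volume_mL` and `consumed_substrate_mg`.
#' @examples
#' tr <- simulate_fedbatch(culture_state(V_R = 50, c_X = 0.03),
#'                         bioprocess_params(c_S0 = 36),
#'                         feed_flow = function(t) 0.0119 * exp(0.1 * t),
#'                         t_end = 5)
#' utils::tail(tr, 1)
#' @export
simulate_fedbatch <- function(initial, params, feed_flow, t_end,
                              dt_out = 0.1, track_volume = FALSE,
                              atol = 1e-10, rtol = 1e-8) {
  if (!inherits(initial, "culture_state"))
    pf_validation_stop("`initial` must be a culture_state")
  if (!inherits(params, "bioprocess_params"))
    pf_validation_stop("`params` must be bioprocess_params")
  if (is.numeric(feed_flow) && length(feed_flow) == 1) {
    const <- feed_flow; feed_flow <- function(t) rep_len(const, length(t))
  }
  if (!is.function(feed_flow))
    pf_validation_stop("`feed_flow` must be a function of time (h) returning mL/h")
  if (!is.numeric(t_end) || length(t_end) != 1 || t_end <= 0)
    pf_validation_stop("`t_end` must be a single positive number of hours")

  q_m <- params$ngam * params$substrate_per_atp  # mg_S mg_CDW^-1 h^-1
  y0 <- c(VS = initial$V_R * initial$c_S,
          VX = initial$V_R * initial$c_X,
          Vdose = 0, Scons = 0)
  derivs <- function(t, y, p) {
    V <- initial$V_R + if (track_volume) y[["Vdose"]] else 0
    cS <- max(y[["VS"]], 0) / V
    cX <- max(y[["VX"]], 0) / V
    vin <- feed_flow(t)
    qS <- params$q_S_max * cS / (params$K_S + cS)
    mu <- params$Y_XS * max(qS - q_m, 0)
    list(c(VS = vin * params$c_S0 - cX * qS * V,
           VX = mu * cX * V,
           Vdose = vin,
           Scons = cX * qS * V))
  }
  times <- unique(c(seq(0, t_end, by = dt_out), t_end))
  sol <- deSolve::lsoda(y0, times, derivs, parms = NULL,
                        atol = atol, rtol = rtol, maxsteps = 50000)
  sol <- as.data.frame(sol)
  neg_tol <- 1e3 * atol * initial$V_R
  if (any(sol$VS < -neg_tol) || any(sol$VX < -neg_tol))
    pf_stop("state went negative beyond tolerance; tighten `atol`/`rtol` or reduce `dt_out`",
            class = "pumpfeed_solver_error")
  V <- initial$V_R + if (track_volume) sol$Vdose else 0
  cS <- pmax(sol$VS, 0) / V
  cX <- pmax(sol$VX, 0) / V
  qS <- params$q_S_max * cS / (params$K_S + cS)
  mu <- params$Y_XS * pmax(qS - q_m, 0)
  out <- data.frame(t_h = sol$time, V_mL = V,
                    cX_mg_per_mL = cX, cS_mg_per_mL = cS,
                    mu_inst_per_h = mu, qS_mg_per_mg_h = qS,
                    dosed_volume_mL = sol$Vdose,
                    consumed_substrate_mg = sol$Scons)
  attr(out, "params") <- params
  attr(out, "initial") <- initial
  class(out) <- c("culture_trajectory", "data.frame")
  out
}

#' Feed-flow functions from a profile or a controller trace
#'
#' `feed_flow_from_profile()` wraps a [feed_profile()]'s closed-form flow
#' as a function of time in hours returning mL h^-1.
#' `feed_flow_from_trace()` differentiates the delivered-volume column of a
#' [simulate_tracking()] trace piecewise, so the culture sees the flow the
#' simulated pump actually delivered (aggregated over `n_syringes`).
#'
#' @param profile a [feed_profile()].
#' @param trace a `control_trace`.
#' @param config the [pump_config()] the trace was simulated with; defaults
#'   to the one attached to the trace.
#' @return A function `f(t_h)` returning the feed flow in mL h^-1.
#' @export
feed_flow_from_profile <- function(profile) {
  if (!inherits(profile, "feed_profile"))
    pf_validation_stop("`profile` must be a feed_profile")
  force(profile)
  function(t_h) per_min_to_per_hour(profile_flow(profile, hours_to_seconds(t_h)))
}

#' @rdname feed_flow_from_profile
#' @param bin_s resampling interval (s) for the trace's cumulative volume
#'   before differentiation. The controller dithers on a seconds scale,
#'   far below the metabolism's response time; binning keeps the ODE
#'   right-hand side piecewise smooth without losing the delivered volume
#'   (the cumulative curve is interpolated, never re-fitted).
#' @export
feed_flow_from_trace <- function(trace, config = attr(trace, "config"),
                                 bin_s = 180) {
  if (!inherits(trace, "control_trace"))
    pf_validation_stop("`trace` must be a control_trace")
  if (!inherits(config, "pump_config"))
    pf_validation_stop("a pump_config is required (none attached to the trace)")
  if (!is.numeric(bin_s) || length(bin_s) != 1 || bin_s <= 0)
    pf_validation_stop("`bin_s` must be a single positive number of seconds")
  t_s <- trace$time_s
  vol_s <- trace$delivered_volume_mL * config$n_syringes
  grid <- sort(unique(c(seq(0, max(t_s), by = bin_s), max(t_s))))
  t_h <- seconds_to_hours(grid)
  vol <- approx(t_s, vol_s, xout = grid, rule = 2)$y
  if (length(t_h) < 2) return(function(t) rep_len(0, length(t)))
  slopes <- diff(vol) / diff(t_h)            # mL/h on each interval
  slopes <- c(slopes, 0)                     # hold 0 after the trace ends
  function(t) {
    k <- findInterval(t, t_h, rightmost.closed = FALSE, all.inside = FALSE)
    out <- numeric(length(t))
    inside <- k >= 1
    out[inside] <- slopes[pmin(k[inside], length(slopes))]
    out
  }
}

#' Estimate a specific growth rate from an exponential series
#'
#' Ordinary least-squares fit of `ln(proxy)` against time; under
#' exponential growth the slope is the specific growth rate. Any positive
#' biomass proxy works (optical density, cell dry weight) since
#' proportionality constants only shift the intercept.
#'
#' @param t sampling times (h), or a two-column data.frame `(t, proxy)`.
#' @param proxy positive biomass-proxy observations.
#' @return A list of class `growth_fit`: `mu_hat` (h^-1), `se`, `intercept`
#'   (log scale), `n`, and the underlying `lm` fit.
#' @examples
#' tt <- seq(0, 10, 1.5)
#' estimate_growth_rate(tt, 0.05 * exp(0.3 * tt))$mu_hat # 0.3
#' @export
estimate_growth_rate <- function(t, proxy = NULL) {
  if (is.data.frame(t)) { proxy <- t[[2]]; t <- t[[1]] }
  if (!is.numeric(t) || !is.numeric(proxy) || length(t) != length(proxy))
    pf_validation_stop("`t` and `proxy` must be numeric vectors of equal length")
  if (length(t) < 3)
    pf_validation_stop("at least 3 observations are required")
  bad <- which(!is.finite(proxy) | proxy <= 0)
  if (length(bad))
    pf_validation_stop("non-positive proxy values at rows: ",
                       paste(bad, collapse = ", "))
  fit <- lm(log(proxy) ~ t)
  sm <- summary(fit)$coefficients
  structure(list(mu_hat = unname(coef(fit)[2]),
                 se = unname(sm["t", "Std. Error"]),
                 intercept = unname(coef(fit)[1]),
                 n = length(t), fit = fit),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> mu_hat = %.4f +/- %.4f h^-1 (n = %d)\n",
              x$mu_hat, x$se, x$n))
  invisible(x)
}

#' Relative discrepancy between achieved and set growth rate
#'
#' @param mu_actual estimated growth rate (h^-1).
#' @param mu_set target growth rate (h^-1), > 0.
#' @return `100 * |mu_actual - mu_set| / mu_set`, in per cent. Vectorised.
#' @examples
#' growth_discrepancy(0.339, 0.3) # 13
#' @export
growth_discrepancy <- function(mu_actual, mu_set) {
  if (!is.numeric(mu_actual) || !is.numeric(mu_set) || any(mu_set <= 0))
    pf_validation_stop("`mu_set` must be positive and both arguments numeric")
  100 * abs(mu_actual - mu_set) / mu_set
}
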