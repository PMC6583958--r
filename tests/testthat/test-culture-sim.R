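test_that("no substrate and no feed means no growth", {
  traj <- simulate_fedbatch(culture_state(V_R = 50, c_X = 0.05, c_S = 0),
                            bioprocess_params(c_S0 = 36),
                            feed_flow = 0, t_end = 5)
  expect_equal(traj$cX_mg_per_mL, rep(0.05, nrow(traj)), tolerance = 1e-9)
  expect_equal(max(traj$consumed_substrate_mg), 0, tolerance = 1e-9)
})

test_that("saturating substrate gives the batch growth limit mu = Y_XS * q_S_max", {
  p <- bioprocess_params(c_S0 = 36)  # K_S = 0.005
  traj <- simulate_fedbatch(culture_state(V_R = 50, c_X = 0.01, c_S = 20),
                            p, feed_flow = 0, t_end = 2)
  expect_equal(traj$mu_inst_per_h[1], p$Y_XS * p$q_S_max, tolerance = 1e-3)
  fit <- estimate_growth_rate(traj$t_h, traj$cX_mg_per_mL)
  expect_equal(fit$mu_hat, p$Y_XS * p$q_S_max, tolerance = 0.01)
})

test_that("an exponential feed sets the intended growth rate under substrate limitation", {
  spec <- fedbatch_spec(0.1, 50, 0.03, 0.35, 36)
  traj <- simulate_fedbatch(
    culture_state(V_R = 50, c_X = 0.03),
    bioprocess_params(c_S0 = 36),
    feed_flow_from_profile(exponential_fedbatch_profile(spec, 10)),
    t_end = 10)
  fit <- estimate_growth_rate(traj$t_h, traj$cX_mg_per_mL)
  expect_lt(growth_discrepancy(fit$mu_hat, 0.1), 2)
  # residual substrate stays far below the feed concentration
  expect_lt(max(traj$cS_mg_per_mL) / 36, 1e-2)
})

test_that("substrate mass is conserved: dosed = pool change + consumed", {
  spec <- fedbatch_spec(0.3, 50, 0.05, 0.35, 18)
  traj <- simulate_fedbatch(
    culture_state(V_R = 50, c_X = 0.05),
    bioprocess_params(c_S0 = 18),
    feed_flow_from_profile(exponential_fedbatch_profile(spec, 6)),
    t_end = 6)
  dosed <- traj$dosed_volume_mL * 18
  pool <- traj$cS_mg_per_mL * traj$V_mL - traj$cS_mg_per_mL[1] * traj$V_mL[1]
  resid <- dosed - (pool + traj$consumed_substrate_mg)
  expect_lt(max(abs(resid)) / max(dosed), 1e-8)
})

test_that("the immediate-consumption limit recovers exponential biomass analytically", {
  # K_S -> 0, q_S_max large: c_X(t) -> c_X0 * exp(mu_set t)
  spec <- fedbatch_spec(0.1, 50, 0.03, 0.35, 36)
  traj <- simulate_fedbatch(
    culture_state(V_R = 50, c_X = 0.03),
    bioprocess_params(c_S0 = 36, K_S = 1e-4, q_S_max = 20),
    feed_flow_from_profile(exponential_fedbatch_profile(spec, 10)),
    t_end = 10)
  analytic <- 0.03 * exp(0.1 * traj$t_h)
  expect_lt(max(abs(traj$cX_mg_per_mL - analytic) / analytic), 1e-3)
})

test_that("volume tracking adds the dosed volume to the vessel", {
  traj <- simulate_fedbatch(culture_state(V_R = 50, c_X = 0.03),
                            bioprocess_params(c_S0 = 36),
                            feed_flow = 1, t_end = 5, track_volume = TRUE)
  expect_equal(traj$V_mL, 50 + traj$t_h, tolerance = 1e-6)
})

test_that("growth-rate estimation is a log-linear fit with informative failures", {
  tt <- seq(0, 9, by = 1.5)
  fit <- suppressWarnings(estimate_growth_rate(tt, 0.05 * exp(0.3 * tt)))
  expect_equal(fit$mu_hat, 0.3, tolerance = 1e-12)
  expect_lt(fit$se, 1e-10)
  flat <- suppressWarnings(estimate_growth_rate(tt, rep(2, length(tt))))
  expect_equal(flat$mu_hat, 0)
  err <- expect_error(estimate_growth_rate(tt, c(1, 2, 0, 4, -1, 6, 7)),
                      class = "pumpfeed_validation_error")
  expect_match(conditionMessage(err), "3, 5")
  expect_error(estimate_growth_rate(c(0, 1), c(1, 2)),
               class = "pumpfeed_validation_error")
  # data.frame input form
  expect_equal(
    suppressWarnings(
      estimate_growth_rate(data.frame(tt, 0.05 * exp(0.2 * tt))))$mu_hat,
    0.2, tolerance = 1e-12)
})

test_that("growth discrepancy is the absolute relative deviation in per cent", {
  expect_identical(growth_discrepancy(0.1, 0.1), 0)
  expect_equal(growth_discrepancy(0.339, 0.3), 13, tolerance = 1e-12)
  expect_error(growth_discrepancy(0.3, 0), class = "pumpfeed_validation_error")
})

test_that("maintenance drains substrate without contributing to growth", {
  p0 <- bioprocess_params(c_S0 = 36)
  pm <- bioprocess_params(c_S0 = 36, ngam = 8.39)
  spec <- fedbatch_spec(0.1, 50, 0.03, 0.35, 36)
  ff <- feed_flow_from_profile(exponential_fedbatch_profile(spec, 8))
  st <- culture_state(V_R = 50, c_X = 0.03)
  x0 <- utils::tail(simulate_fedbatch(st, p0, ff, 8)$cX_mg_per_mL, 1)
  xm <- utils::tail(simulate_fedbatch(st, pm, ff, 8)$cX_mg_per_mL, 1)
  expect_lt(xm, x0)                 # maintenance costs biomass
  expect_gt(xm, 0.8 * x0)           # but is a small correction at this scale
})
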