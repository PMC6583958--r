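test_that("segment volumes are exact closed-form integrals", {
  expect_equal(segment_volume(constant_segment(0.5, 600), 600), 5)
  expect_equal(segment_volume(ramp_segment(0, 0.5, 600), 600), 2.5)
  # exponential fed-batch segment: b * (exp(a t) - 1), oracle evaluated inline
  b <- 50 * 0.03 / (0.35 * 36)
  seg <- exponential_segment(b = b, a = 0.1, duration = hours_to_seconds(10))
  expect_equal(segment_volume(seg, hours_to_seconds(10)),
               b * (exp(1) - 1), tolerance = 1e-12)
  expect_equal(round(segment_volume(seg, hours_to_seconds(10)), 4), 0.2046)
  expect_error(segment_volume(seg, hours_to_seconds(11)),
               class = "pumpfeed_domain_error")
  expect_error(segment_volume(seg, -5), class = "pumpfeed_domain_error")
})

test_that("exponential fed-batch profile carries the feed-law parameters", {
  spec <- fedbatch_spec(0.1, V_R = 50, c_X0 = 0.03, Y_XS = 0.35, c_S0 = 36)
  pr <- exponential_fedbatch_profile(spec, t_end = 10)
  seg <- pr$segments[[1]]
  expect_equal(seg$params$b, 0.1190476, tolerance = 1e-6)
  expect_equal(seg$params$a, 0.1)
  # initial flow mu * b (mL/h), profile reports mL/min
  expect_equal(profile_flow(pr, 0), per_hour_to_per_min(0.1 * seg$params$b))
  expect_equal(round(0.1 * seg$params$b, 4), 0.0119)

  spec4 <- fedbatch_spec(0.4, 50, 0.04, 0.35, 36)
  pr4 <- exponential_fedbatch_profile(spec4, 7)
  expect_equal(round(pr4$segments[[1]]$params$b, 4), 0.1587)
})

test_that("fed-batch spec validation enforces positivity and plausibility", {
  expect_error(fedbatch_spec(-0.1, 50, 0.03, 0.35, 36),
               class = "pumpfeed_validation_error")
  expect_error(fedbatch_spec(0.1, 50, 0.03, 0, 36),
               class = "pumpfeed_validation_error")
  expect_error(fedbatch_spec(2.5, 50, 0.03, 0.35, 36),
               class = "pumpfeed_validation_error")
  expect_warning(fedbatch_spec(0.8, 50, 0.03, 0.35, 36), "typical range")
})

test_that("b-factor sizes an exponential feed to a target total volume", {
  expect_equal(b_factor(4.375, a = 1, T_h = 5), 4.375 * exp(-5))
  expect_equal(round(b_factor(4.375, 1, 5), 5), 0.02948)
  expect_equal(b_factor(2, a = 0, T_h = 5), 2)
  # round trip: the sized segment reaches the target exactly
  b <- b_factor(4.375, 1, 5)
  seg <- exponential_segment(b, 1, hours_to_seconds(5))
  # validation convention: dosed volume measured from the initial set point
  expect_equal(b * exp(1 * 5), 4.375, tolerance = 1e-12)
  expect_equal(segment_volume(seg, hours_to_seconds(5)) + b, 4.375,
               tolerance = 1e-12)
})

test_that("compiled schedules are additive over segments and exact at boundaries", {
  cfg <- pump_config(standard_syringe("50 mL"), gear_train(0), r_S = 90)
  two <- feed_profile(list(constant_segment(0.5, 600),
                           constant_segment(0.25, 600)))
  sch <- compile_schedule(two, cfg, dt = 30)
  expect_equal(max(sch$cumulative_volume_mL), 7.5)
  expect_equal(sch$cumulative_volume_mL[sch$time_s == 600], 5)
  # refinement invariance: boundary volumes do not depend on dt
  for (dt in c(7, 30, 123)) {
    s <- compile_schedule(two, cfg, dt = dt)
    expect_true(all(c(600, 1200) %in% s$time_s))
    expect_equal(s$cumulative_volume_mL[s$time_s == 600], 5)
    expect_equal(s$cumulative_volume_mL[s$time_s == 1200], 7.5)
  }
})

test_that("compiled exponential schedule chains the feed law into rotation", {
  cfg <- cfg_10ml()  # gdf 576, r_S 90, l_V 8
  spec <- fedbatch_spec(0.1, 50, 0.03, 0.35, 36)
  sch <- compile_schedule(exponential_fedbatch_profile(spec, 10), cfg)
  vol10 <- 50 * 0.03 / (0.35 * 36) * (exp(1) - 1)
  final <- sch[nrow(sch), ]
  expect_equal(final$cumulative_volume_mL, vol10, tolerance = 1e-12)
  expect_equal(final$set_rotation_deg, vol10 * 576 * 90 * 8, tolerance = 1e-12)
  # schedule invariant: set_rotation = volume * gdf * r_S * l_V at every row
  expect_equal(sch$set_rotation_deg, sch$cumulative_volume_mL * 414720,
               tolerance = 1e-12)
  expect_false(is.unsorted(sch$set_rotation_deg))
})

test_that("an empty profile compiles to a single zero row", {
  sch <- compile_schedule(feed_profile(), cfg_10ml())
  expect_equal(nrow(sch), 1)
  expect_equal(unlist(sch[1, c("time_s", "set_rotation_deg",
                               "cumulative_volume_mL", "flow_mL_min")]),
               c(time_s = 0, set_rotation_deg = 0,
                 cumulative_volume_mL = 0, flow_mL_min = 0))
})

test_that("flow is the derivative of cumulative volume on every grid point", {
  # central differences of the closed-form volume against the stated flow
  spec <- fedbatch_spec(0.3, 50, 0.05, 0.35, 18)
  pr <- exponential_fedbatch_profile(spec, 5)
  t <- seq(30, hours_to_seconds(5) - 30, by = 300)
  h <- 1e-3
  num <- (profile_volume(pr, t + h) - profile_volume(pr, t - h)) / (2 * h) * 60
  expect_equal(num, profile_flow(pr, t), tolerance = 1e-9)
  # ramp segment too
  pr2 <- feed_profile(ramp_segment(0.1, 0.6, 1200))
  t2 <- seq(10, 1190, by = 50)
  num2 <- (profile_volume(pr2, t2 + h) - profile_volume(pr2, t2 - h)) / (2 * h) * 60
  expect_equal(num2, profile_flow(pr2, t2), tolerance = 1e-9)
})

test_that("gradient pair conserves the total flow exactly", {
  gp <- gradient_pair(0.5, T = 1200)
  t <- seq(0, 1200, by = 60)
  expect_identical(profile_flow(gp$down, t) + profile_flow(gp$up, t),
                   rep(0.5, length(t)))
  expect_equal(profile_flow(gp$down, 600), 0.25)
  expect_equal(profile_flow(gp$down, 0), 0.5)
  expect_equal(profile_flow(gp$up, 0), 0)
  # conservation of compiled volume
  cfg <- pump_config(standard_syringe("50 mL"), gear_train(0), r_S = 90)
  vd <- max(compile_schedule(gp$down, cfg)$cumulative_volume_mL)
  vu <- max(compile_schedule(gp$up, cfg)$cumulative_volume_mL)
  expect_equal(vd + vu, 0.5 * 1200 / 60, tolerance = 1e-12)
})

test_that("purification program phases follow the 4/5/10/2 CV protocol", {
  pp <- purification_program(column_volume = 1, flow = 0.5)
  # phase durations 8, 10, 20, 4 minutes
  expect_equal(pp$phases$end_s[pp$phases$phase == "load"], 8 * 60)
  expect_equal(diff(unlist(pp$phases[pp$phases$phase == "wash",
                                     c("start_s", "end_s")])),
               c(end_s = 10 * 60))
  total_dur <- profile_duration(pp$A)
  expect_equal(total_dur, 42 * 60)
  expect_true(all(vapply(pp[c("B", "C", "D")], profile_duration,
                         numeric(1)) == total_dur))
  # channel volumes: A exactly 4 CV, program total 21 CV
  expect_equal(profile_volume(pp$A, total_dur), 4)
  tot <- sum(vapply(pp[c("A", "B", "C", "D")],
                    function(p) profile_volume(p, total_dur), numeric(1)))
  expect_equal(tot, 21)
  # column inflow is constant at every instant of the program
  t <- seq(0, total_dur, by = 15)
  inflow <- Reduce(`+`, lapply(pp[c("A", "B", "C", "D")], profile_flow, t))
  expect_equal(inflow[-length(inflow)], rep(0.5, length(t) - 1))
})
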