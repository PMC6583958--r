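test_that("origin-constrained yield fitting recovers exact linear data", {
  qs <- seq(0.2, 1.4, length.out = 8)
  # exact data: the perfect-fit warning from summary.lm is expected here
  expect_equal(suppressWarnings(fit_yield(mu_qs_dataset(qs, 0.35 * qs)))$yield,
               0.35, tolerance = 1e-12)
  expect_equal(suppressWarnings(fit_yield(mu_qs_dataset(qs, 0.263 * qs)))$yield,
               0.263, tolerance = 1e-12)
  expect_error(fit_yield(mu_qs_dataset(0.5, 0.2)),
               class = "pumpfeed_validation_error")
})

test_that("yield fitting on noisy data has near-nominal 3-SE coverage", {
  qs <- seq(0.2, 1.4, length.out = 12)
  within3 <- vapply(1:20, function(s) {
    f <- fit_yield(synth_mu_qs(0.35, qs, sigma_rel = 0.05, seed = s))
    abs(f$yield - 0.35) < 3 * f$se
  }, logical(1))
  # noise is relative (heteroscedastic), so the plain OLS SE is only
  # approximate; nearly all draws still land within 3 SE
  expect_gte(sum(within3), 18)
  # estimator consistency: vanishing noise removes the bias entirely
  d0 <- synth_mu_qs(0.35, qs, sigma_rel = 0, seed = 42)
  expect_lt(abs(suppressWarnings(fit_yield(d0))$yield - 0.35), 1e-10)
})

test_that("intercept mode reports an implied maintenance rate", {
  qs <- seq(0.2, 1.4, length.out = 10)
  # mu = Y * (q_S - q_m): intercept fit recovers q_m
  d <- mu_qs_dataset(qs, 0.35 * (qs - 0.05))
  f <- suppressWarnings(fit_yield(d, intercept = TRUE))
  expect_equal(f$yield, 0.35, tolerance = 1e-10)
  expect_equal(f$implied_maintenance, 0.05, tolerance = 1e-8)
})

test_that("strain filtering selects the right records", {
  qs <- seq(0.2, 1.2, length.out = 6)
  d <- rbind(synth_mu_qs(0.35, qs, 0, seed = 1, strain = "wildtype"),
             synth_mu_qs(0.263, qs, 0, seed = 2, strain = "loaded"))
  expect_equal(suppressWarnings(fit_yield(d, strain = "wildtype"))$yield,
               0.35, tolerance = 1e-12)
  expect_equal(suppressWarnings(fit_yield(d, strain = "loaded"))$yield,
               0.263, tolerance = 1e-12)
})

test_that("burden decomposition reproduces the load/total/share identities", {
  res <- burden_decomposition(0.35, 0.263)
  expect_equal(res$load_fraction_of_growth, 0.33, tolerance = 0.01)
  expect_equal(res$total_fraction, 1.33, tolerance = 0.01)
  expect_equal(res$load_share_of_total, 0.25, tolerance = 0.01)
  none <- burden_decomposition(0.4, 0.4)
  expect_identical(none$load_fraction_of_growth, 0)
  expect_identical(none$total_fraction, 1)
  expect_error(burden_decomposition(0.35, 0),
               class = "pumpfeed_validation_error")
  expect_warning(burden_decomposition(0.3, 0.35), "negative burden")
})

test_that("decomposition identities hold for all yield pairs, and burden is monotone", {
  yw <- 0.35
  yl_grid <- seq(0.05, 0.35, length.out = 25)
  loads <- vapply(yl_grid, function(yl) {
    r <- burden_decomposition(yw, yl)
    expect_equal(r$total_fraction - r$load_fraction_of_growth, 1,
                 tolerance = 1e-15)
    expect_equal(r$load_share_of_total,
                 r$load_fraction_of_growth / (1 + r$load_fraction_of_growth),
                 tolerance = 1e-15)
    r$load_fraction_of_growth
  }, numeric(1))
  expect_true(all(diff(loads) < 0))  # decreases as Y_loaded rises toward Y_WT
})

test_that("uncertainty propagates by the delta method and bootstrap agrees", {
  r <- burden_decomposition(0.35, 0.263, se_WT = 0.005, se_loaded = 0.005,
                            bootstrap = 4000, seed = 9)
  # delta method: sqrt((se_W/Yl)^2 + (Yw*se_l/Yl^2)^2)
  expect_equal(r$load_fraction_se,
               sqrt((0.005 / 0.263)^2 + (0.35 * 0.005 / 0.263^2)^2),
               tolerance = 1e-12)
  ci <- r$load_fraction_boot_ci
  expect_lt(ci[1], r$load_fraction_of_growth)
  expect_gt(ci[2], r$load_fraction_of_growth)
  expect_equal(diff(ci), 2 * 1.96 * r$load_fraction_se, tolerance = 0.15)
  expect_error(burden_decomposition(0.35, 0.263, bootstrap = 100),
               class = "pumpfeed_validation_error")
})

test_that("bead volume is the enclosed sphere volume in microlitres", {
  expect_identical(bead_volume(0), 0)
  expect_equal(bead_volume(1), pi / 6)
  expect_equal(round(bead_volume(1), 4), 0.5236)
  expect_equal(bead_volume(2.92), 13.036, tolerance = 1e-4)
})

test_that("bead size statistics are the sample mean and SD", {
  expect_equal(bead_size_stats(c(2, 2, 2)), list(mean = 2, sd = 0, n = 3L))
  s <- bead_size_stats(c(2.7, 3.1))
  expect_equal(s$mean, 2.9)
  expect_equal(round(s$sd, 4), 0.2828)
  expect_error(bead_size_stats(2.9), class = "pumpfeed_validation_error")
})
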