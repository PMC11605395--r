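test_that("with no variability every replicate equals the typical profile", {
  p <- tab2_params()
  sim <- simulate_population("q8w_900", p, zero_re(), n = 20, seed = 1,
                             horizon_weeks = 24)
  typ <- conc_profile(build_regimen("q8w_900", horizon_weeks = 24), p,
                      sim$times)
  for (i in 1:5) expect_equal(sim$conc[i, ], typ, tolerance = 1e-12)
  pct <- sim$percentiles
  # all percentile bands collapse onto the median
  spread <- tapply(pct$conc, pct$time, function(x) diff(range(x)))
  expect_true(all(spread < 1e-9))
})

test_that("percentiles are monotone in probability and reproducible under seed", {
  sim <- simulate_population("q8w_900", n = 400, seed = 11, horizon_weeks = 24)
  for (t in unique(sim$percentiles$time)) {
    q <- sim$percentiles$conc[sim$percentiles$time == t]
    expect_true(all(diff(q) >= 0))
  }
  sim2 <- simulate_population("q8w_900", n = 400, seed = 11,
                              horizon_weeks = 24)
  expect_identical(sim$conc, sim2$conc)
  sim3 <- simulate_population("q8w_900", n = 400, seed = 12,
                              horizon_weeks = 24)
  expect_false(identical(sim$conc, sim3$conc))
})

test_that("trough summaries: threshold logic and grid validation", {
  sim <- simulate_population("q8w_900", n = 500, seed = 2, horizon_weeks = 24)
  cs <- ctrough_summary(sim, weeks = c(8, 16), thresholds = c(0, 24, 32, 50))
  expect_equal(cs$above_0, c(1, 1))
  # attainment is non-increasing in the threshold
  expect_true(all(cs$above_24 >= cs$above_32))
  expect_true(all(cs$above_32 >= cs$above_50))
  expect_true(all(cs$pi_lo <= cs$median & cs$median <= cs$pi_hi))
  expect_error(ctrough_summary(sim, weeks = 100), "grid")
})

test_that("population median tracks the typical profile at trough times", {
  p <- tab2_params()
  # with BSV on CL alone the trough is monotone in the single eta, so the
  # lognormal median property transfers exactly to the simulated median
  re_cl <- rpv_re(omega_F_oral = 0, omega_ka_slow = 0,
                  omega_F_im_fast = 0, omega_IOV_CL = 0)
  sim <- simulate_population("q8w_900", p, re_cl, n = 5000, seed = 3,
                             horizon_weeks = 48)
  wk <- c(8, 16, 24, 32, 40, 48)
  cs <- ctrough_summary(sim, weeks = wk)
  typ <- conc_profile(build_regimen("q8w_900", horizon_weeks = 48), p,
                      wk * 168)
  expect_equal(cs$median, typ, tolerance = 0.03)
  # under the full variability the trough is non-monotone in eta_ka_slow
  # (large omega), so the median sits below the typical curve late in the
  # horizon; it stays within ~10%
  sim2 <- simulate_population("q8w_900", p, tab2_re(), n = 5000, seed = 3,
                              horizon_weeks = 48)
  cs2 <- ctrough_summary(sim2, weeks = wk)
  expect_lt(max(abs(cs2$median - typ) / typ), 0.10)
})

test_that("median trough dips at week 16 and then rises through week 48", {
  sim <- simulate_population("q8w_900", n = 3000, seed = 4,
                             horizon_weeks = 48)
  cs <- ctrough_summary(sim, weeks = c(8, 16, 24, 32, 40, 48))
  expect_lt(cs$median[2], cs$median[1])
  expect_true(all(diff(cs$median[-1]) > 0))
})

test_that("doubling the cohort leaves the median within Monte-Carlo tolerance", {
  s1 <- simulate_population("q8w_900", n = 1500, seed = 5, horizon_weeks = 16)
  s2 <- simulate_population("q8w_900", n = 3000, seed = 6, horizon_weeks = 16)
  m1 <- ctrough_summary(s1, 16)$median
  m2 <- ctrough_summary(s2, 16)$median
  expect_equal(m1, m2, tolerance = 0.06)
})

test_that("sex contrast vanishes without a covariate effect", {
  sx <- sex_contrast(theta_female = 0, weeks = c(8, 24, 48), n = 300,
                     seed = 7)
  expect_equal(sx$pct_diff, rep(0, 3), tolerance = 1e-12)
})

test_that("residual noise is added only when requested", {
  s0 <- simulate_population("q8w_900", n = 50, seed = 8, horizon_weeks = 8)
  s1 <- simulate_population("q8w_900", n = 50, seed = 8, horizon_weeks = 8,
                            residual = TRUE)
  expect_false(identical(s0$conc, s1$conc))
  expect_true(all(s1$conc >= 0))
})
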