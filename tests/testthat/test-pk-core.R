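test_that("disposition micro-constants match direct algebra", {
  p <- tab2_params()
  d <- disposition_constants(p)
  expect_equal(d$k10, 6.74 / 277, tolerance = 1e-12)
  expect_equal(d$k21, 4.08 / 839, tolerance = 1e-12)
  expect_equal(round(d$k10, 5), 0.02433)
  expect_equal(round(d$k21, 6), 0.004863)
})

test_that("macro eigenvalues satisfy the Vieta identities and limits", {
  set.seed(1)
  for (i in 1:50) {
    f <- runif(4, 0.5, 1.5)
    p <- suppressWarnings(rpv_params(CL = 6.74 * f[1], V3 = 277 * f[2],
                                     Q = 4.08 * f[3], V4 = 839 * f[4]))
    d <- disposition_constants(p)
    expect_equal(d$lambda1 * d$lambda2, d$k10 * d$k21, tolerance = 1e-10)
    expect_equal(d$lambda1 + d$lambda2, d$k10 + d$k12 + d$k21,
                 tolerance = 1e-10)
  }
  # one-compartment limit
  p0 <- suppressWarnings(rpv_params(Q = 0))
  d0 <- disposition_constants(p0)
  expect_equal(d0$lambda1, d0$k10, tolerance = 1e-12)
  expect_equal(d0$lambda2, 0, tolerance = 1e-15)
  expect_error(disposition_constants(rpv_params(CL = -1)), "positive")
})

test_that("biphasic oral half-lives agree with an eigendecomposition oracle", {
  p <- tab2_params()
  d <- disposition_constants(p)
  # independent oracle: eigenvalues of the 2x2 disposition matrix
  A <- matrix(c(-(d$k10 + d$k12), d$k21, d$k12, -d$k21), 2, 2, byrow = TRUE)
  ev <- sort(-eigen(A)$values, decreasing = TRUE)
  th <- biphasic_half_lives(p)
  expect_equal(unname(th), log(2) / ev, tolerance = 1e-10)
  expect_equal(round(unname(th)), c(17, 240))
  # bioavailability does not enter the disposition rates
  p2 <- rpv_params(F_oral = 0.1)
  expect_equal(biphasic_half_lives(p2), th)
  expect_error(biphasic_half_lives(suppressWarnings(rpv_params(Q = 0))),
               "terminal")
})

test_that("IM terminal half-life and time to steady state follow ka_slow", {
  expect_equal(round(terminal_half_life_im(0.000229), 1), 18.0)
  expect_equal(terminal_half_life_im(log(2) / 168), 1)
  expect_equal(round(terminal_half_life_im(0.00214), 2), 1.93)
  expect_error(terminal_half_life_im(-1), "positive")
  expect_warning(terminal_half_life_im(0.01, tab2_params()), "flip-flop")

  expect_equal(round(time_to_steady_state(0.000229), 1), 1.7)
  expect_equal(time_to_steady_state(0.000229, n_half_lives = 0), 0)
  expect_equal(time_to_steady_state(0.000229 / 2),
               2 * time_to_steady_state(0.000229))
})

test_that("population interval of the IM half-life matches the lognormal quantiles", {
  ci <- halflife_interval(0.000229, 82.7)
  sigma <- sqrt(log(1 + 0.827^2))
  t_typ <- log(2) / 0.000229 / 168
  expect_equal(unname(ci), t_typ * exp(c(-1, 1) * qnorm(0.95) * sigma),
               tolerance = 1e-12)
  expect_equal(round(unname(ci), 1), c(5.5, 59.1))
  # log-symmetry about the typical value and the zero-variance limit
  expect_equal(sqrt(prod(ci)), t_typ, tolerance = 1e-12)
  expect_equal(unname(halflife_interval(0.000229, 0)), rep(t_typ, 2))
})

test_that("closed-form profile is linear in dose and ignores future doses", {
  p <- tab2_params()
  reg <- build_regimen("q8w_900", horizon_weeks = 24)
  tt <- seq(0, 24 * 168, by = 200)
  base <- conc_profile(reg, p, tt)
  reg2 <- reg; reg2$amount <- 2.5 * reg2$amount
  expect_equal(conc_profile(reg2, p, tt), 2.5 * base, tolerance = 1e-14)
  # two identical doses at the same time == one double dose
  r1 <- single_im_regimen(450)
  r2 <- rbind(r1, r1)
  expect_equal(conc_profile(r2, p, tt), conc_profile(single_im_regimen(900), p, tt),
               tolerance = 1e-12)
  # times at or before the first dose give zero
  expect_identical(conc_profile(reg, p, c(0)), 0)
  bad <- reg; bad$route[1] <- "iv"
  expect_error(conc_profile(bad, p, tt), "route")
  expect_error(conc_profile(reg, p, c(-1, 10)), ">= 0")
})

test_that("oral steady-state average concentration equals F dose / (CL tau)", {
  p <- tab2_params()
  reg <- oral_qd_regimen(days = 120)
  tt <- seq(119 * 24, 120 * 24, by = 0.25)
  avg <- mean(conc_profile(reg, p, tt))
  expect_equal(avg, 25000 * 0.654 / (6.74 * 24), tolerance = 0.01)
})

test_that("terminal log-slope after a single IM dose reflects ka_slow (flip-flop)", {
  p <- tab2_params()
  tt <- seq(20, 100, by = 2) * 168
  lc <- log(conc_profile(single_im_regimen(), p, tt))
  slope <- unname(coef(lm(lc ~ tt))[2])
  expect_equal(slope, -p$ka_slow, tolerance = 0.01)
})

test_that("compiled kernel, pure-R reference and population kernel agree", {
  p <- tab2_params()
  reg <- build_regimen("q8w_900", horizon_weeks = 30)
  tt <- seq(10, 30 * 168, length.out = 60)
  kap <- c(0.2, -0.1, 0.05, 0, 0.1, -0.3)
  a <- conc_profile(reg, p, tt, kappa = kap)
  b <- rilpk:::conc_profile_r(reg, p, tt, kappa = kap)
  expect_equal(a, b, tolerance = 1e-12)
  pars <- list(CL = rep(p$CL, 2), V3 = rep(p$V3, 2), Q = rep(p$Q, 2),
               V4 = rep(p$V4, 2), ka_fast = rep(p$ka_fast, 2),
               ka_slow = rep(p$ka_slow, 2), F_im_fast = rep(p$F_im_fast, 2),
               F_oral = rep(p$F_oral, 2))
  km <- rbind(kap, kap)
  pop <- rilpk:::conc_profile_pop(reg, pars, tt, kappa_mat = km)
  expect_equal(pop[1, ], a, tolerance = 1e-12)
  expect_equal(pop[2, ], a, tolerance = 1e-12)
})

test_that("ODE oracle matches the closed form on the study regimen", {
  p <- tab2_params()
  reg <- build_regimen("q8w_900", horizon_weeks = 48)
  tt <- seq(24, 48 * 168, by = 7 * 24)
  cc <- conc_profile(reg, p, tt)
  co <- conc_profile_ode(reg, p, tt)
  expect_lt(max(abs(cc - co) / pmax(co, 1e-9)), 1e-3)
  expect_error(conc_profile_ode(reg, p, tt, rtol = -1), "positive")
})

test_that("ODE solution conserves mass and is zero without doses", {
  p <- tab2_params()
  reg <- build_regimen("q8w_900", horizon_weeks = 8)
  mb <- conc_profile_ode(reg, p, c(1000, 2000, 8 * 168), mass_balance = TRUE)
  expect_equal(mb$in_system + mb$eliminated, mb$delivered, tolerance = 1e-6)
  empty <- build_regimen("q8w_900", horizon_weeks = 8)[0, ]
  expect_identical(conc_profile_ode(empty, p, c(10, 100)), c(0, 0))
})

test_that("closed form matches the ODE oracle over random parameters and regimens", {
  set.seed(7)
  for (i in 1:60) {
    f <- runif(9, 0.5, 1.5)
    p <- suppressWarnings(rpv_params(6.74 * f[1], 277 * f[2], 4.08 * f[3],
                                     839 * f[4], 0.00214 * f[5],
                                     0.000229 * f[6],
                                     min(max(0.276 * f[7], 0.05), 0.95),
                                     0.654 * f[8], 4 * f[9]))
    n_or <- sample(1:4, 1); n_im <- sample(1:3, 1)
    reg <- rbind(
      data.frame(time = sort(runif(n_or, 0, 240)), amount = 25, route = "oral",
                 duration = p$D_oral, occasion = NA_integer_),
      data.frame(time = sort(runif(n_im, 0, 4000)), amount = 900, route = "im",
                 duration = 0, occasion = seq_len(n_im)))
    reg <- reg[order(reg$time), ]
    tt <- sort(runif(12, 0, 6000))
    cc <- conc_profile(reg, p, tt)
    co <- conc_profile_ode(reg, p, tt)
    expect_lt(max(abs(cc - co) / pmax(abs(co), 1e-6)), 1e-3)
  }
})
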