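test_that("zero-variance OFV equals the exact fixed-effect normal likelihood", {
  p <- tab2_params()
  reg <- single_im_regimen()
  tt <- c(336, 1000, 1500)
  f <- conc_profile(reg, p, tt)
  set.seed(5)
  yy <- f * exp(rnorm(3, 0, 0.2))
  tab <- make_table(reg, tt, yy)
  re <- zero_re(sigma_prop = 0.2)
  v <- (0.2 * f)^2
  exact <- sum(log(2 * pi * v) + (yy - f)^2 / v)
  expect_equal(ofv(tab, p, re, iov = FALSE), exact, tolerance = 1e-10)
})

test_that("Laplace OFV matches an adaptive-quadrature oracle on toy problems", {
  p <- tab2_params()
  reg <- data.frame(time = c(0, 672), amount = 900, route = "im",
                    duration = 0, occasion = c(1L, 2L))
  for (case in 1:3) {
    set.seed(case)
    nt <- c(1, 3, 5)[case]
    tt <- sort(runif(nt, 200, 2500))
    f <- conc_profile(reg, p, tt)
    yy <- f * exp(rnorm(nt, 0, 0.2))
    tab <- make_table(reg, tt, yy)
    omega <- c(0.3, 0.4, 0.6)[case]
    re <- rpv_re(omega_F_oral = 0, omega_ka_slow = 0, omega_CL = omega,
                 omega_F_im_fast = 0, omega_IOV_CL = 0, sigma_prop_im = 0.2)
    o_lap <- ofv(tab, p, re, re_structure = "CL", iov = FALSE)
    lik <- function(eta) {
      vapply(eta, function(e) {
        fe <- rilpk:::conc_profile_cpp(reg$time, reg$amount, c(1L, 1L),
                                       reg$duration, c(0, 0), tt,
                                       p$CL * exp(e), p$V3, p$Q, p$V4,
                                       p$ka_fast, p$ka_slow, p$F_im_fast,
                                       p$F_oral)
        prod(dnorm(yy, fe, 0.2 * fe)) * dnorm(e, 0, omega)
      }, numeric(1))
    }
    o_quad <- -2 * log(integrate(lik, -4, 4, rel.tol = 1e-10)$value)
    expect_lt(abs(o_lap - o_quad), 0.5)
  }
})

test_that("OFV is invariant to subject order", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 10, n_rich = 5),
                         re = matched_re(), seed = 13)
  p <- tab2_params(); re <- matched_re()
  o1 <- ofv(coh$data, p, re, re_structure = c("CL", "ka_slow", "F_im_fast"),
            iov = FALSE)
  perm <- coh$data[order(-coh$data$ID, coh$data$TIME, -coh$data$EVID), ]
  o2 <- ofv(perm, p, re, re_structure = c("CL", "ka_slow", "F_im_fast"),
            iov = FALSE)
  expect_equal(o1, o2, tolerance = 1e-8)
})

test_that("a refit with an extra free parameter never worsens the OFV", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 20, n_rich = 10),
                         re = matched_re(), seed = 17)
  args <- list(data = coh$data, init = tab2_params(), init_re = matched_re(),
               estimate_re = "CL", estimate_sigma = "prop_im",
               re_structure = c("CL", "ka_slow", "F_im_fast"), iov = FALSE)
  red <- do.call(fit_popmodel, c(args, list(estimate = "CL")))
  full <- do.call(fit_popmodel,
                  c(list(data = coh$data, init = red$params,
                         init_re = red$re, estimate = c("CL", "F_im_fast"),
                         estimate_re = "CL", estimate_sigma = "prop_im",
                         re_structure = c("CL", "ka_slow", "F_im_fast"),
                         iov = FALSE)))
  expect_lte(full$ofv, red$ofv + 1e-6)
})

test_that("the fit recovers clearance exactly on noise-free data", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 15, n_rich = 8),
                         re = zero_re(), seed = 19, residual = FALSE)
  fit <- fit_popmodel(coh$data, init = rpv_params(CL = 10),
                      init_re = zero_re(sigma_add = 1, sigma_prop = 0.02),
                      estimate = "CL", estimate_re = character(),
                      estimate_sigma = character(),
                      re_structure = character(), iov = FALSE)
  expect_equal(fit$params$CL, 6.74, tolerance = 0.01)
})

test_that("delta-OFV tests use the chi-square thresholds of the selection procedure", {
  # sex on F_im_fast: drop of 11 points is significant even at the 0.001 level
  t1 <- delta_ofv_test(100, 89, df = 1, alpha = 0.001)
  expect_true(t1$significant)
  expect_lt(t1$p_value, 0.001)
  # boundary: 3.83 misses the 3.84 criterion
  expect_false(delta_ofv_test(100, 96.17, df = 1, alpha = 0.05)$significant)
  expect_true(delta_ofv_test(100, 96.15, df = 1, alpha = 0.05)$significant)
  # a drop of 6 does not survive the backward threshold of 6.63
  expect_false(delta_ofv_test(100, 94, df = 1, alpha = 0.01)$significant)
  expect_error(delta_ofv_test(100, 99, df = 0), "df")
})

test_that("shrinkage summarises the collapse of empirical-Bayes effects", {
  expect_equal(shrinkage_pct(rep(0, 20), 0.3), 100)
  set.seed(2)
  eta <- rnorm(5000, 0, 0.3)
  expect_equal(shrinkage_pct(eta, 0.3), 0, tolerance = 3)
  expect_error(shrinkage_pct(eta, 0), "> 0")
})

test_that("rich sampling shrinks empirical-Bayes effects less than sparse sampling", {
  p <- tab2_params(); re <- matched_re()
  fit_one <- function(n_rich, seed) {
    coh <- simulate_cohort(cohort_spec(n_subjects = 20, n_rich = n_rich),
                           re = re, seed = seed)
    fit <- fit_popmodel(coh$data, init = p, init_re = re,
                        estimate = "F_im_fast", estimate_re = character(),
                        estimate_sigma = character(),
                        re_structure = c("CL", "ka_slow", "F_im_fast"),
                        iov = FALSE)
    shrinkage_pct(fit$eta_hat[, "F_im_fast"], re$omega_F_im_fast)
  }
  expect_lt(fit_one(n_rich = 20, seed = 23), fit_one(n_rich = 0, seed = 23))
})

test_that("bootstrap machinery: identity replicate, stratification, reproducibility", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 12, n_rich = 6),
                         re = matched_re(), seed = 29)
  args <- list(init = tab2_params(), init_re = matched_re(),
               estimate = "CL", estimate_re = "CL",
               estimate_sigma = "prop_im",
               re_structure = c("CL", "ka_slow", "F_im_fast"), iov = FALSE)
  orig <- do.call(fit_popmodel, c(list(data = coh$data), args))
  bid <- do.call(bootstrap_fit, c(list(data = coh$data, n_replicates = 1,
                                       seed = 1, identity = TRUE), args))
  expect_equal(bid$estimates$CL, orig$params$CL, tolerance = 1e-6)
  # stratified resampling preserves the stratum counts exactly
  ids <- unique(coh$data$ID)
  sex <- vapply(ids, function(id) coh$data$SEX[coh$data$ID == id][1],
                numeric(1))
  b1 <- do.call(bootstrap_fit, c(list(data = coh$data, n_replicates = 2,
                                      seed = 3, stratify = "SEX"), args))
  expect_equal(b1$n_failed, 0)
  b2 <- do.call(bootstrap_fit, c(list(data = coh$data, n_replicates = 2,
                                      seed = 3, stratify = "SEX"), args))
  expect_identical(b1$estimates, b2$estimates)
  expect_error(bootstrap_fit(coh$data, n_replicates = 0), ">= 1")
})

test_that("bootstrap CI covers the true clearance on a synthetic cohort", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 25, n_rich = 12),
                         re = matched_re(), seed = 37)
  b <- bootstrap_fit(coh$data, n_replicates = 30, seed = 5, stratify = "SEX",
                     init = tab2_params(), init_re = matched_re(),
                     estimate = "CL", estimate_re = "CL",
                     estimate_sigma = "prop_im",
                     re_structure = c("CL", "ka_slow", "F_im_fast"),
                     iov = FALSE)
  row <- b$summary[b$summary$parameter == "CL", ]
  expect_gt(6.74, row$ci_lo)
  expect_lt(6.74, row$ci_hi)
})
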