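test_that("demographics reproduce the study table's sex ratio, medians and ranges", {
  set.seed(3)
  dem <- generate_demographics(cohort_spec(n_subjects = 5000, n_rich = 28))
  expect_equal(mean(dem$SEX), 0.20, tolerance = 0.10)
  expect_equal(median(dem$AGE), 46, tolerance = 0.05)
  expect_equal(median(dem$WT), 78, tolerance = 0.05)
  expect_equal(median(dem$BMI), 25.4, tolerance = 0.05)
  expect_true(all(dem$AGE >= 20 & dem$AGE <= 79))
  expect_true(all(dem$WT >= 50 & dem$WT <= 126))
  expect_true(all(dem$BMI >= 18.2 & dem$BMI <= 43.3))
  set.seed(4)
  one <- generate_demographics(cohort_spec(n_subjects = 1, fraction_female = 1))
  expect_identical(one$SEX, 1L)
  expect_error(cohort_spec(n_subjects = 0), ">= 1")
})

test_that("q8w template places injections at weeks 4, 8 then every 8 weeks", {
  reg <- build_regimen("q8w_900", horizon_weeks = 48)
  im <- reg[reg$route == "im", ]
  expect_equal(im$time / 168, c(4, 8, 16, 24, 32, 40, 48))
  expect_equal(im$amount, rep(900, 7))
  expect_equal(im$occasion, c(1:6, 6L))  # capped at six occasions
  oral <- reg[reg$route == "oral", ]
  expect_equal(nrow(oral), 28)
  expect_equal(oral$amount[1], 25)
  # long horizon: all late injections share occasion 6
  reg2 <- build_regimen("q8w_900", horizon_weeks = 104)
  expect_equal(max(reg2$occasion, na.rm = TRUE), 6L)
  # no injections before week 4
  reg0 <- build_regimen("q8w_900", horizon_weeks = 0)
  expect_true(all(reg0$route == "oral"))
  reg4 <- build_regimen("q4w_600", horizon_weeks = 16)
  im4 <- reg4[reg4$route == "im", ]
  expect_equal(im4$time / 168, c(4, 8, 12, 16))
  expect_equal(im4$amount, rep(600, 4))
  expect_error(build_regimen("weekly"), "arg")
})

test_that("rich subjects are sampled across one maintenance interval", {
  set.seed(5)
  reg <- build_regimen("q8w_900", horizon_weeks = 48)
  samp <- generate_sampling(reg, rich = TRUE)
  # rich design: oral trough + IM troughs + 1/2/4-week post-injection samples
  expect_gte(nrow(samp), 5)
  im_times <- reg$time[reg$route == "im"]
  gaps <- vapply(samp$time, function(t) t - max(im_times[im_times <= t] , -Inf),
                 numeric(1))
  # at least the 1- and 2-week post-injection samples exist
  expect_true(any(gaps > 100 & gaps < 240))
  expect_true(any(gaps > 270 & gaps < 410))
  empty <- reg[0, ]
  expect_equal(nrow(generate_sampling(empty, rich = TRUE)), 0)
})

test_that("cohort sampling has a median of about four samples per subject", {
  coh <- simulate_cohort(cohort_spec(), seed = 21)
  obs <- coh$data[coh$data$EVID == 0, ]
  counts <- table(obs$ID)
  expect_gte(median(counts), 3)
  expect_lte(median(counts), 5)
  expect_equal(length(unique(coh$data$ID)), 238)
  # most samples are troughs below typical oral levels; all flagged vs LLOQ
  expect_true(all(obs$BLQ %in% c(0L, 1L)))
})

test_that("cohort observations equal typical predictions when variability is off", {
  coh <- simulate_cohort(cohort_spec(n_subjects = 8, n_rich = 4),
                         re = zero_re(), seed = 2, residual = FALSE)
  obs <- coh$data[coh$data$EVID == 0, ]
  pred <- population_predict(coh$data, tab2_params())
  expect_equal(obs$DV, pred, tolerance = 1e-10)
})

test_that("censoring flags follow the LLOQ", {
  spec_hi <- cohort_spec(n_subjects = 6, n_rich = 0, lloq = 1e9)
  coh <- simulate_cohort(spec_hi, seed = 3)
  expect_true(all(coh$data$BLQ[coh$data$EVID == 0] == 1L))
  spec_lo <- cohort_spec(n_subjects = 6, n_rich = 0, lloq = 1e-9)
  coh2 <- simulate_cohort(spec_lo, seed = 3)
  expect_true(all(coh2$data$BLQ[coh2$data$EVID == 0] == 0L))
})

test_that("generation is deterministic under a fixed seed", {
  a <- simulate_cohort(cohort_spec(n_subjects = 12), seed = 7)
  b <- simulate_cohort(cohort_spec(n_subjects = 12), seed = 7)
  expect_identical(a$data, b$data)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(cohort_spec(n_subjects = 12), seed = 8)
  expect_false(identical(a$data, c$data))
})

test_that("about 15% of oral troughs fall below 50 ng/mL under the fitted variability", {
  coh <- simulate_cohort(cohort_spec(), seed = 31)
  obs <- coh$data[coh$data$EVID == 0 & coh$data$ROUTE == "oral", ]
  frac <- mean(obs$DV < 50)
  expect_gt(frac, 0.07)
  expect_lt(frac, 0.27)
})
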