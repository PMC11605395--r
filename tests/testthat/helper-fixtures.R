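# shared fixtures: the published parameter set, small event tables and
# cohort wrappers used across test files

tab2_params <- function() rpv_params()
tab2_re <- function() rpv_re()

# variability restricted to the terms a reduced fit carries, so that
# estimation experiments are correctly specified
matched_re <- function() rpv_re(omega_F_oral = 0, omega_IOV_CL = 0)

zero_re <- function(sigma_add = 18, sigma_prop = 0.18) {
  rpv_re(omega_F_oral = 0, omega_ka_slow = 0, omega_CL = 0,
         omega_F_im_fast = 0, omega_IOV_CL = 0,
         sigma_add_oral = sigma_add, sigma_prop_im = sigma_prop)
}

# one-subject event table from a regimen and observation vectors
make_table <- function(regimen, obs_time, dv, id = 1, sex = 0, lloq = 5) {
  route <- vapply(obs_time, function(t) {
    prior <- regimen$time <= t
    regimen$route[max(which(prior))]
  }, character(1))
  occ_of <- function(t) {
    prior <- which(regimen$route == "im" & regimen$time <= t)
    if (!length(prior)) NA_integer_ else regimen$occasion[max(prior)]
  }
  dose_rows <- data.frame(ID = id, TIME = regimen$time, AMT = regimen$amount,
                          DV = NA_real_, EVID = 1L,
                          CMT = ifelse(regimen$route == "im", 2L, 1L),
                          MDV = 1L, ROUTE = regimen$route,
                          DUR = regimen$duration, OCC = regimen$occasion,
                          BLQ = 0L)
  obs_rows <- data.frame(ID = id, TIME = obs_time, AMT = NA_real_, DV = dv,
                         EVID = 0L, CMT = 1L, MDV = 0L, ROUTE = route,
                         DUR = NA_real_,
                         OCC = vapply(obs_time, occ_of, integer(1)),
                         BLQ = as.integer(dv < lloq))
  out <- rbind(dose_rows, obs_rows)
  out <- out[order(out$TIME, -out$EVID), ]
  out$SEX <- sex; out$AGE <- 46; out$WT <- 78; out$BMI <- 25.4
  out$LLOQ <- lloq
  rownames(out) <- NULL
  out
}

single_im_regimen <- function(amount = 900) {
  data.frame(time = 0, amount = amount, route = "im", duration = 0,
             occasion = 1L, stringsAsFactors = FALSE)
}

oral_qd_regimen <- function(days = 120, dose = 25) {
  data.frame(time = seq(0, by = 24, length.out = days), amount = dose,
             route = "oral", duration = 4, occasion = NA_integer_,
             stringsAsFactors = FALSE)
}
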