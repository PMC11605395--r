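# Laplace-approximation nonlinear mixed-effects estimation for the
# rilpivirine model: per-subject empirical-Bayes (inner) optimisation of
# the random effects, outer optimisation of fixed effects and variance
# components on log/logit scales, and the model-selection machinery
# (delta-OFV tests, stepwise covariate search, bootstrap, shrinkage).

BSV_NAMES <- c("CL", "F_oral", "ka_slow", "F_im_fast")
omega_field <- function(nm) paste0("omega_", nm)

# split an event-record table into per-subject structures; BLQ and
# missing observations are excluded from the likelihood
prep_subjects <- function(table) {
  ids <- unique(table$ID)
  lapply(ids, function(id) {
    st <- table[table$ID == id, , drop = FALSE]
    doses <- st[st$EVID == 1, , drop = FALSE]
    obs <- st[st$EVID == 0 & st$MDV == 0 & st$BLQ == 0, , drop = FALSE]
    occ <- doses$OCC
    occ[is.na(occ)] <- 0L
    relevant <- if (nrow(obs)) {
      sort(unique(occ[occ > 0 & doses$TIME < max(obs$TIME)]))
    } else integer()
    occ_idx <- match(occ, relevant, nomatch = 0L)  # 0 = no IOV on this dose
    list(id = id,
         obs_time = obs$TIME, y = obs$DV,
         oral_obs = obs$ROUTE == "oral",
         covariates = c(SEX = st$SEX[1], AGE = st$AGE[1],
                        WT = st$WT[1], BMI = st$BMI[1]),
         cpp = list(dt = doses$TIME, da = doses$AMT,
                    rc = as.integer(doses$ROUTE == "im"),
                    du = ifelse(is.na(doses$DUR), 0, doses$DUR),
                    oi = occ_idx, nocc = length(relevant),
                    ot = obs$TIME, y = obs$DV,
                    oral = as.integer(obs$ROUTE == "oral")))
  })
}

cov_theta_star <- function(F_im_fast, cov_spec, covariates) {
  th <- F_im_fast
  for (k in seq_along(cov_spec$names)) {
    x <- covariates[[cov_spec$names[k]]]
    th <- th * (1 + cov_spec$theta[k] * (x - cov_spec$ref[k]))
  }
  th
}

# Laplace -2 log marginal likelihood, summed over subjects. `active`
# names the BSV terms with free etas; IOV adds one kappa per relevant
# occasion. The per-subject inner problems are solved by a damped-Newton
# scheme in compiled code, always started from eta = 0, so the value is
# a deterministic smooth function of the population parameters.
ofv_impl <- function(subs, params, re, active, iov, cov_spec,
                     want_eta = FALSE, ...) {
  codes <- c(CL = 0L, F_oral = 1L, ka_slow = 2L, F_im_fast = 3L)
  w2_bsv <- vapply(active, function(nm) re[[omega_field(nm)]]^2, numeric(1))
  lgth <- vapply(subs, function(s) {
    th <- cov_theta_star(params$F_im_fast, cov_spec, s$covariates)
    if (th <= 0 || th >= 1) NA_real_ else stats::qlogis(th)
  }, numeric(1))
  if (any(is.na(lgth))) {
    if (want_eta) stop("covariate-adjusted F_im_fast outside (0, 1)",
                       call. = FALSE)
    return(Inf)
  }
  res <- ofv_cpp(lapply(subs, `[[`, "cpp"), lgth,
                 params$CL, params$V3, params$Q, params$V4,
                 params$ka_fast, params$ka_slow, params$F_oral,
                 re$sigma_add_oral^2, re$sigma_prop_im^2,
                 unname(codes[active]), unname(w2_bsv),
                 iov && re$omega_IOV_CL > 0, re$omega_IOV_CL^2, want_eta)
  if (!want_eta) return(res$ofv)
  eta <- res$eta
  colnames(eta) <- active
  list(ofv = res$ofv, eta = eta)
}

#' Objective function value (Laplace -2 log marginal likelihood)
#'
#' Computes the population objective function for an event-record table
#' at given parameter values: per subject, the marginal likelihood over
#' the random effects is approximated by Laplace's method around the
#' empirical-Bayes mode (found by quasi-Newton optimisation); with all
#' variability terms zero it reduces to the exact fixed-effect normal
#' likelihood. BLQ records are excluded.
#'
#' @param data event-record data frame (see [read_pk_dataset()]).
#' @param params typical [rpv_params()].
#' @param re an [rpv_re()] specification.
#' @param re_structure BSV terms carrying random effects (subset of
#'   `c("CL", "F_oral", "ka_slow", "F_im_fast")`); terms with zero omega
#'   are dropped.
#' @param iov include per-occasion IOV on clearance.
#' @param covariates optional covariate columns acting linearly on
#'   `F_im_fast` (see [fit_popmodel()]).
#' @param theta_cov,cov_ref covariate coefficients and reference values
#'   (parallel to `covariates`).
#' @return The OFV (scalar).
#' @export
ofv <- function(data, params, re, re_structure = BSV_NAMES, iov = TRUE,
                covariates = character(), theta_cov = numeric(),
                cov_ref = numeric()) {
  subs <- prep_subjects(data)
  active <- re_structure[vapply(re_structure,
                                function(nm) re[[omega_field(nm)]] > 0,
                                logical(1))]
  cov_spec <- list(names = covariates, theta = theta_cov, ref = cov_ref)
  ofv_impl(subs, params, re, active, iov, cov_spec)
}

#' Likelihood-ratio test between nested models
#'
#' Compares the OFV drop of a full model against the chi-square quantile
#' with `df` degrees of freedom: at `alpha = 0.05` and `df = 1` the
#' critical drop is 3.84, at `alpha = 0.01` it is 6.63.
#'
#' @param ofv_reduced,ofv_full objective function values of the nested
#'   pair.
#' @param df number of additional parameters in the full model.
#' @param alpha significance level.
#' @return List with `delta_ofv`, `critical`, `significant`, `p_value`.
#' @export
delta_ofv_test <- function(ofv_reduced, ofv_full, df = 1, alpha = 0.05) {
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  delta <- ofv_full - ofv_reduced
  crit <- stats::qchisq(1 - alpha, df)
  list(delta_ofv = delta, critical = crit,
       significant = delta < -crit,
       p_value = stats::pchisq(max(-delta, 0), df, lower.tail = FALSE))
}

#' Eta shrinkage
#'
#' `100 (1 - SD(eta_hat) / omega)`: the degree to which empirical-Bayes
#' effects collapse toward zero under sparse designs.
#'
#' @param eta_hat empirical-Bayes estimates of one random effect.
#' @param omega the population SD of that effect.
#' @return Shrinkage in percent.
#' @export
shrinkage_pct <- function(eta_hat, omega) {
  if (omega <= 0) stop("omega must be > 0", call. = FALSE)
  100 * (1 - stats::sd(eta_hat, na.rm = TRUE) / omega)
}

pack_start <- function(init, init_re, estimate, estimate_re, estimate_sigma,
                       covariates, beta_init = NULL) {
  x <- numeric(0)
  for (nm in estimate) {
    x <- c(x, if (nm == "F_im_fast") stats::qlogis(init[[nm]])
           else log(init[[nm]]))
  }
  for (nm in estimate_re) {
    om <- if (nm == "IOV") init_re$omega_IOV_CL else init_re[[omega_field(nm)]]
    if (om <= 0) stop("cannot estimate a zero initial omega: ", nm,
                      call. = FALSE)
    x <- c(x, log(om))
  }
  for (nm in estimate_sigma) {
    x <- c(x, log(init_re[[paste0("sigma_", nm)]]))
  }
  if (is.null(beta_init)) beta_init <- rep(0, length(covariates))
  x <- c(x, beta_init)
  names(x) <- c(estimate,
                if (length(estimate_re)) paste0("omega_", estimate_re),
                if (length(estimate_sigma)) paste0("sigma_", estimate_sigma),
                if (length(covariates)) paste0("beta_", covariates))
  x
}

unpack_par <- function(x, init, init_re, estimate, estimate_re,
                       estimate_sigma, covariates) {
  p <- unclass(init); re <- unclass(init_re)
  i <- 0
  for (nm in estimate) {
    i <- i + 1
    p[[nm]] <- unname(if (nm == "F_im_fast") stats::plogis(x[i]) else exp(x[i]))
  }
  for (nm in estimate_re) {
    i <- i + 1
    if (nm == "IOV") re$omega_IOV_CL <- unname(exp(x[i]))
    else re[[omega_field(nm)]] <- unname(exp(x[i]))
  }
  for (nm in estimate_sigma) {
    i <- i + 1
    re[[paste0("sigma_", nm)]] <- unname(exp(x[i]))
  }
  theta_cov <- if (length(covariates)) x[i + seq_along(covariates)]
               else numeric()
  list(params = structure(p, class = "rpv_params"),
       re = structure(re, class = "rpv_re"),
       theta_cov = unname(theta_cov))
}

#' Fit the population model by Laplace-approximate maximum likelihood
#'
#' Maximises the Laplace-approximated marginal likelihood over the
#' selected fixed effects (log scale; `F_im_fast` on the logit scale),
#' variance components (log scale) and optional covariate coefficients,
#' with `D_oral` always fixed. The inner random-effect modes are found by
#' quasi-Newton optimisation started from zero and warm-started across
#' outer iterations; the outer problem uses `nlminb`.
#'
#' @param data event-record data frame.
#' @param init initial/fixed typical values ([rpv_params()]).
#' @param init_re initial/fixed variability terms ([rpv_re()]). Terms not
#'   estimated stay fixed at these values.
#' @param estimate fixed effects to estimate.
#' @param estimate_re variance components to estimate (subset of the BSV
#'   names plus `"IOV"`).
#' @param estimate_sigma residual components to estimate (subset of
#'   `c("add_oral", "prop_im")`).
#' @param re_structure BSV terms present in the model.
#' @param iov include IOV on clearance.
#' @param covariates covariate columns entering `F_im_fast` as linear
#'   fractional effects `theta (1 + beta (x - ref))`; `ref` is 0 for 0/1
#'   covariates and the cohort median otherwise.
#' @param beta_init starting values for the covariate coefficients
#'   (default all zero).
#' @param se compute standard errors (finite-difference Hessian) and RSE.
#' @param control list: `iter_max`, `eval_max`, `rel_tol`, `inner_maxit`.
#' @return An object of class `rpv_fit`: estimates, OFV, empirical-Bayes
#'   effects, convergence diagnostics, and (optionally) SE/RSE.
#' @export
fit_popmodel <- function(data, init = rpv_params(), init_re = rpv_re(),
                         estimate = c("CL", "F_im_fast", "ka_slow"),
                         estimate_re = c("CL", "ka_slow", "F_im_fast"),
                         estimate_sigma = "prop_im",
                         re_structure = c("CL", "ka_slow", "F_im_fast"),
                         iov = FALSE, covariates = character(),
                         beta_init = NULL, se = FALSE, control = list()) {
  ctl <- utils::modifyList(list(iter_max = 150, eval_max = 500,
                                rel_tol = 1e-8, inner_maxit = 100), control)
  subs <- prep_subjects(data)
  if (length(subs) < 3) {
    warning("fewer than 3 subjects: the design is unlikely to be identifiable",
            call. = FALSE)
  }
  cov_ref <- vapply(covariates, function(nm) {
    vals <- vapply(subs, function(s) s$covariates[[nm]], numeric(1))
    if (all(vals %in% c(0, 1))) 0 else stats::median(vals)
  }, numeric(1))

  start <- pack_start(init, init_re, estimate, estimate_re, estimate_sigma,
                      covariates, beta_init)

  outer_obj <- function(x) {
    u <- unpack_par(x, init, init_re, estimate, estimate_re, estimate_sigma,
                    covariates)
    active <- re_structure[vapply(re_structure,
                                  function(nm) u$re[[omega_field(nm)]] > 0,
                                  logical(1))]
    cov_spec <- list(names = covariates, theta = u$theta_cov, ref = cov_ref)
    val <- tryCatch(ofv_impl(subs, u$params, u$re, active, iov, cov_spec),
                    error = function(e) Inf)
    if (!is.finite(val)) 1e10 else val
  }

  opt <- stats::nlminb(start, outer_obj,
                       control = list(iter.max = ctl$iter_max,
                                      eval.max = ctl$eval_max,
                                      rel.tol = ctl$rel_tol))
  u <- unpack_par(opt$par, init, init_re, estimate, estimate_re,
                  estimate_sigma, covariates)
  active <- re_structure[vapply(re_structure,
                                function(nm) u$re[[omega_field(nm)]] > 0,
                                logical(1))]
  cov_spec <- list(names = covariates, theta = u$theta_cov, ref = cov_ref)
  fin <- ofv_impl(subs, u$params, u$re, active, iov, cov_spec,
                  want_eta = TRUE)

  se_tab <- NULL
  if (se) {
    H <- tryCatch(stats::optimHess(opt$par, outer_obj), error = function(e) NULL)
    if (!is.null(H)) {
      cv <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(cv)) {
        se_t <- sqrt(pmax(diag(cv), 0))
        est_nat <- vapply(names(start), function(nm) {
          if (nm %in% estimate) u$params[[sub("^", "", nm)]]
          else if (grepl("^omega_", nm)) {
            k <- sub("omega_", "", nm)
            if (k == "IOV") u$re$omega_IOV_CL else u$re[[omega_field(k)]]
          } else if (grepl("^sigma_", nm)) u$re[[nm]]
          else u$theta_cov[match(sub("beta_", "", nm), covariates)]
        }, numeric(1))
        rse <- ifelse(grepl("^beta_", names(start)),
                      100 * se_t / abs(est_nat),
                      ifelse(names(start) == "F_im_fast",
                             100 * (1 - u$params$F_im_fast) * se_t,
                             100 * se_t))
        se_tab <- data.frame(parameter = names(start), estimate = est_nat,
                             se_transformed = se_t, rse_percent = rse)
      }
    }
  }

  structure(list(params = u$params, re = u$re,
                 theta_cov = stats::setNames(u$theta_cov, covariates),
                 cov_ref = cov_ref, covariates = covariates,
                 ofv = fin$ofv, eta_hat = fin$eta,
                 convergence = opt$convergence, message = opt$message,
                 n_subjects = length(subs),
                 n_obs = sum(vapply(subs, function(s) length(s$y), numeric(1))),
                 estimate = estimate, estimate_re = estimate_re,
                 estimate_sigma = estimate_sigma,
                 re_structure = re_structure, iov = iov,
                 se = se_tab),
            class = "rpv_fit")
}

#' @export
print.rpv_fit <- function(x, ...) {
  cat("Population PK fit (Laplace)\n")
  cat(sprintf("  subjects %d, observations %d, OFV %.3f\n",
              x$n_subjects, x$n_obs, x$ofv))
  cat("  estimates:\n")
  for (nm in x$estimate) cat(sprintf("    %-10s %.4g\n", nm, x$params[[nm]]))
  for (nm in x$estimate_re) {
    om <- if (nm == "IOV") x$re$omega_IOV_CL else x$re[[omega_field(nm)]]
    cat(sprintf("    omega_%-6s %.4g (CV %.1f%%)\n", nm, om, cv_from_omega(om)))
  }
  for (nm in x$estimate_sigma) {
    cat(sprintf("    sigma_%-6s %.4g\n", nm, x$re[[paste0("sigma_", nm)]]))
  }
  if (length(x$theta_cov)) {
    for (k in seq_along(x$theta_cov)) {
      cat(sprintf("    beta_%-7s %.4g\n", names(x$theta_cov)[k], x$theta_cov[k]))
    }
  }
  invisible(x)
}

#' Stepwise covariate selection on the fast-pathway fraction
#'
#' Classic forward-insertion (`alpha = 0.05`, critical delta-OFV 3.84) /
#' backward-deletion (`alpha = 0.01`, critical 6.63) search over candidate
#' covariates entering `F_im_fast` as linear fractional effects.
#'
#' @inheritParams fit_popmodel
#' @param candidates covariate column names to screen.
#' @param alpha_forward,alpha_backward significance levels of the two
#'   passes.
#' @param ... passed to [fit_popmodel()].
#' @return List with `log` (data frame of steps: phase, candidate,
#'   delta_ofv, decision), `included` (final covariate set) and
#'   `final_fit`.
#' @export
stepwise_covariates <- function(data, candidates = c("SEX", "AGE", "WT", "BMI"),
                                alpha_forward = 0.05, alpha_backward = 0.01,
                                ...) {
  steps <- list()
  note <- function(phase, cand, delta, decision) {
    steps[[length(steps) + 1]] <<- data.frame(phase = phase, candidate = cand,
                                              delta_ofv = delta,
                                              decision = decision)
  }
  fits <- new.env(parent = emptyenv())
  # nested fits are warm-started from the current model so a model with
  # an extra coefficient can never converge above its nested parent
  fit_with <- function(covs, from = NULL) {
    key <- paste0("m:", paste(sort(covs), collapse = "+"))
    if (is.null(fits[[key]])) {
      extra <- list(data = data, covariates = covs)
      if (!is.null(from)) {
        extra$init <- from$params
        extra$init_re <- from$re
        extra$beta_init <- unname(ifelse(covs %in% names(from$theta_cov),
                                         from$theta_cov[covs], 0))
      }
      fits[[key]] <- do.call(fit_popmodel,
                             utils::modifyList(list(...), extra))
    }
    fits[[key]]
  }

  current <- character()
  cur_fit <- fit_with(current)
  remaining <- candidates
  crit_f <- stats::qchisq(1 - alpha_forward, 1)
  repeat {
    if (!length(remaining)) break
    deltas <- vapply(remaining, function(cand) {
      fit_with(c(current, cand), from = cur_fit)$ofv - cur_fit$ofv
    }, numeric(1))
    best <- which.min(deltas)
    sig <- deltas < -crit_f
    for (k in seq_along(remaining)) {
      note("forward", remaining[k], deltas[k],
           if (k == best && sig[k]) "added"
           else if (sig[k]) "significant, not best" else "not significant")
    }
    if (!sig[best]) break
    current <- c(current, remaining[best])
    cur_fit <- fit_with(current)
    remaining <- remaining[-best]
  }

  crit_b <- stats::qchisq(1 - alpha_backward, 1)
  repeat {
    if (!length(current)) break
    deltas <- vapply(current, function(cand) {
      fit_with(setdiff(current, cand), from = cur_fit)$ofv - cur_fit$ofv
    }, numeric(1))
    worst <- which.min(deltas)  # smallest OFV increase on removal
    if (deltas[worst] <= crit_b) {
      note("backward", current[worst], deltas[worst], "removed")
      current <- setdiff(current, current[worst])
      cur_fit <- fit_with(current)
    } else {
      for (k in seq_along(current)) {
        note("backward", current[k], deltas[k], "retained")
      }
      break
    }
  }

  list(log = do.call(rbind, steps), included = current, final_fit = cur_fit)
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement (optionally stratified, preserving
#' stratum counts exactly), refits each replicate and summarises the
#' estimates by their median and 2.5/97.5 percentiles. Non-converged or
#' failed replicates are excluded and counted.
#'
#' @inheritParams fit_popmodel
#' @param n_replicates number of bootstrap replicates.
#' @param seed integer seed.
#' @param stratify optional covariate column defining resampling strata
#'   (e.g. `"SEX"`); `NULL` for unstratified.
#' @param identity if `TRUE`, every "resample" is the original cohort
#'   (testing hook: a single identity replicate must reproduce the
#'   original fit).
#' @param ... passed to [fit_popmodel()].
#' @return List with `estimates` (replicate x parameter data frame),
#'   `summary` (median and CI95 per parameter), `n_failed`.
#' @export
bootstrap_fit <- function(data, n_replicates = 200, seed = 1,
                          stratify = "SEX", identity = FALSE, ...) {
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  set.seed(seed)
  ids <- unique(data$ID)
  strat <- if (is.null(stratify)) rep(1, length(ids)) else {
    vapply(ids, function(id) data[[stratify]][data$ID == id][1], numeric(1))
  }
  flatten <- function(fit) {
    out <- c(unlist(fit$params[fit$estimate]),
             stats::setNames(vapply(fit$estimate_re, function(nm) {
               if (nm == "IOV") fit$re$omega_IOV_CL
               else fit$re[[omega_field(nm)]]
             }, numeric(1)), paste0("omega_", fit$estimate_re)),
             stats::setNames(vapply(fit$estimate_sigma, function(nm) {
               fit$re[[paste0("sigma_", nm)]]
             }, numeric(1)),
             if (length(fit$estimate_sigma)) paste0("sigma_", fit$estimate_sigma)),
             fit$theta_cov)
    out
  }
  reps <- vector("list", n_replicates)
  n_failed <- 0
  for (r in seq_len(n_replicates)) {
    take <- if (identity) ids else {
      unlist(lapply(unique(strat), function(g) {
        pool <- ids[strat == g]
        sample(pool, length(pool), replace = TRUE)
      }))
    }
    pieces <- lapply(seq_along(take), function(j) {
      st <- data[data$ID == take[j], , drop = FALSE]
      st$ID <- j
      st
    })
    boot_data <- do.call(rbind, pieces)
    fit <- tryCatch(fit_popmodel(boot_data, ...), error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$ofv)) {
      n_failed <- n_failed + 1
    } else {
      reps[[r]] <- flatten(fit)
    }
  }
  est <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  if (is.null(est)) stop("all bootstrap replicates failed", call. = FALSE)
  est <- as.data.frame(est)
  summ <- data.frame(parameter = names(est),
                     median = vapply(est, stats::median, numeric(1)),
                     ci_lo = vapply(est, stats::quantile, numeric(1),
                                    probs = 0.025),
                     ci_hi = vapply(est, stats::quantile, numeric(1),
                                    probs = 0.975))
  rownames(summ) <- NULL
  list(estimates = est, summary = summ, n_failed = n_failed)
}

#' Individual (empirical-Bayes) predictions for an event-record table
#'
#' Predicted concentrations at every observation record using each
#' subject's empirical-Bayes random-effect modes under the given
#' population model (modes are estimated from the subject's non-BLQ
#' observations; subjects with no usable observations fall back to the
#' typical prediction).
#'
#' @inheritParams ofv
#' @param theta_female optional sex effect on `F_im_fast`.
#' @return Numeric vector, one value per observation row of `data` (in
#'   table order, including BLQ rows).
#' @export
individual_predict <- function(data, params, re, re_structure = BSV_NAMES,
                               iov = FALSE, theta_female = 0) {
  subs <- prep_subjects(data)
  active <- re_structure[vapply(re_structure,
                                function(nm) re[[omega_field(nm)]] > 0,
                                logical(1))]
  cov_spec <- if (theta_female != 0) {
    list(names = "SEX", theta = theta_female, ref = 0)
  } else {
    list(names = character(), theta = numeric(), ref = numeric())
  }
  fin <- ofv_impl(subs, params, re, active, iov, cov_spec, want_eta = TRUE)
  ids <- unique(data$ID)
  preds <- rep(NA_real_, sum(data$EVID == 0))
  ptr <- 0
  for (k in seq_along(ids)) {
    st <- data[data$ID == ids[k], , drop = FALSE]
    doses <- st[st$EVID == 1, , drop = FALSE]
    obs <- st[st$EVID == 0, , drop = FALSE]
    if (!nrow(obs)) next
    g <- function(nm) {
      if (!nm %in% active) return(0)
      v <- fin$eta[k, nm]
      if (is.na(v)) 0 else v
    }
    th_star <- cov_theta_star(params$F_im_fast, cov_spec,
                              subs[[k]]$covariates)
    f <- conc_profile_cpp(doses$TIME, doses$AMT,
                          as.integer(doses$ROUTE == "im"),
                          ifelse(is.na(doses$DUR), 0, doses$DUR),
                          numeric(nrow(doses)), obs$TIME,
                          params$CL * exp(g("CL")), params$V3, params$Q,
                          params$V4, params$ka_fast,
                          params$ka_slow * exp(g("ka_slow")),
                          stats::plogis(stats::qlogis(th_star) +
                                        g("F_im_fast")),
                          params$F_oral * exp(g("F_oral")))
    preds[ptr + seq_len(nrow(obs))] <- f
    ptr <- ptr + nrow(obs)
  }
  preds
}

#' Typical-value (population) predictions for an event-record table
#'
#' Predicted concentration at every observation record with all random
#' effects at zero, optionally applying the sex covariate on
#' `F_im_fast`.
#'
#' @param data event-record data frame.
#' @param params typical [rpv_params()].
#' @param theta_female optional fractional sex effect on `F_im_fast`.
#' @return Numeric vector, one value per observation row of `data`
#'   (in table order, including BLQ rows).
#' @export
population_predict <- function(data, params, theta_female = 0) {
  ids <- unique(data$ID)
  preds <- rep(NA_real_, sum(data$EVID == 0))
  ptr <- 0
  for (id in ids) {
    st <- data[data$ID == id, , drop = FALSE]
    doses <- st[st$EVID == 1, , drop = FALSE]
    obs <- st[st$EVID == 0, , drop = FALSE]
    if (!nrow(obs)) next
    p_i <- params
    if (theta_female != 0 && st$SEX[1] == 1) {
      p_i <- suppressWarnings(do.call(rpv_params, utils::modifyList(
        unclass(params),
        list(F_im_fast = fimfast_individual(params$F_im_fast, 0, TRUE,
                                            theta_female)))))
    }
    reg <- data.frame(time = doses$TIME, amount = doses$AMT,
                      route = doses$ROUTE,
                      duration = ifelse(is.na(doses$DUR), 0, doses$DUR),
                      occasion = doses$OCC, stringsAsFactors = FALSE)
    preds[ptr + seq_len(nrow(obs))] <- conc_profile(reg, p_i, obs$TIME)
    ptr <- ptr + nrow(obs)
  }
  preds
}
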