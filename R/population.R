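#' Random-effects and residual-error specification
#'
#' Holds the variability terms of the hierarchical model: lognormal
#' between-subject variability (BSV) SDs on `F_oral`, `ka_slow` and `CL`,
#' a logit-scale BSV SD on `F_im_fast`, a lognormal inter-occasion
#' variability (IOV) SD on `CL` (re-drawn at each IM injection occasion),
#' and the residual error components (additive for oral records,
#' proportional for IM records). Defaults are the final model estimates;
#' the `omega_*` values are SDs on the transformed scale, with CV%
#' representations available through [cv_from_omega()] and
#' [fimfast_cv_approx()].
#'
#' @param omega_F_oral,omega_ka_slow,omega_CL log-scale BSV SDs.
#' @param omega_F_im_fast logit-scale BSV SD on the fast-pathway fraction.
#' @param omega_IOV_CL log-scale IOV SD on clearance.
#' @param sigma_add_oral additive residual SD for oral records, ng/mL.
#' @param sigma_prop_im proportional residual SD for IM records (fraction).
#' @return An object of class `rpv_re` (a named list).
#' @export
rpv_re <- function(omega_F_oral = omega_from_cv(37.1),
                   omega_ka_slow = omega_from_cv(82.7),
                   omega_CL = omega_from_cv(25.9),
                   omega_F_im_fast = 0.168 / (1 - 0.276),
                   omega_IOV_CL = omega_from_cv(13.0),
                   sigma_add_oral = 18,
                   sigma_prop_im = 0.18) {
  re <- list(omega_F_oral = omega_F_oral, omega_ka_slow = omega_ka_slow,
             omega_CL = omega_CL, omega_F_im_fast = omega_F_im_fast,
             omega_IOV_CL = omega_IOV_CL, sigma_add_oral = sigma_add_oral,
             sigma_prop_im = sigma_prop_im)
  bad <- names(re)[vapply(re, function(x) !is.numeric(x) || length(x) != 1L ||
                            !is.finite(x) || x < 0, logical(1))]
  if (length(bad)) {
    stop("variability terms must be non-negative scalars: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(re, class = "rpv_re")
}

#' Convert a lognormal SD to a coefficient of variation (and back)
#'
#' For a lognormal random effect with log-scale SD `omega`,
#' `CV% = 100 sqrt(exp(omega^2) - 1)`; `omega_from_cv` is the exact
#' inverse.
#'
#' @param omega log-scale SD.
#' @param cv_percent coefficient of variation, percent.
#' @return `cv_from_omega`: CV in percent; `omega_from_cv`: log-scale SD.
#' @export
cv_from_omega <- function(omega) {
  if (any(omega < 0)) stop("omega must be >= 0", call. = FALSE)
  100 * sqrt(exp(omega^2) - 1)
}

#' @rdname cv_from_omega
#' @export
omega_from_cv <- function(cv_percent) {
  if (any(cv_percent < 0)) stop("cv_percent must be >= 0", call. = FALSE)
  sqrt(log(1 + (cv_percent / 100)^2))
}

#' Individual fast-pathway fraction on the logit scale
#'
#' The fraction of an IM dose absorbed through the fast depot is kept in
#' (0, 1) by modelling it on the logit scale: with
#' `theta* = theta (1 + theta_female female)`,
#' `TEMP = log(theta* / (1 - theta*))` and the individual value is
#' `plogis(TEMP + eta)`. The optional sex covariate acts as a fractional
#' change on the typical value inside the logit.
#'
#' @param theta typical fast-pathway fraction, in (0, 1).
#' @param eta individual logit-scale random effect (vectorised).
#' @param female logical (or 0/1) covariate flag, vectorised.
#' @param theta_female fractional change in females (e.g. -0.456 for a
#'   45.6% reduction).
#' @return Individual fraction(s) in (0, 1).
#' @examples
#' fimfast_individual(0.276)                             # typical male
#' fimfast_individual(0.276, female = TRUE, theta_female = -0.456)
#' @export
fimfast_individual <- function(theta, eta = 0, female = FALSE,
                               theta_female = 0) {
  theta_star <- theta * (1 + theta_female * as.numeric(female))
  if (any(theta_star <= 0 | theta_star >= 1)) {
    stop("covariate-adjusted fraction must lie in (0, 1)", call. = FALSE)
  }
  stats::plogis(stats::qlogis(theta_star) + eta)
}

#' Delta-method CV of the fast-pathway fraction
#'
#' First-order approximation of the CV of `F_im_fast` induced by a
#' logit-scale BSV SD `omega_eta`: `CV% = 100 (1 - theta) omega_eta`
#' (the SD of the logistic transform is about
#' `theta (1 - theta) omega_eta`, divided by the mean `theta`).
#'
#' @param theta typical fraction in (0, 1).
#' @param omega_eta logit-scale SD.
#' @return CV in percent.
#' @export
fimfast_cv_approx <- function(theta, omega_eta) {
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)", call. = FALSE)
  100 * (1 - theta) * omega_eta
}

#' Individual parameters from typical values and random effects
#'
#' Applies the hierarchical model: `CL`, `F_oral` and `ka_slow` carry
#' lognormal BSV (`x_i = x exp(eta)`), `F_im_fast` logit-scale BSV via
#' [fimfast_individual()] (with the optional sex covariate), and `CL`
#' additionally carries a per-occasion IOV term `exp(kappa)` when an
#' occasion is specified. `F_oral` is deliberately not truncated at 1:
#' individual values above 1 are interpreted as oral-to-IM relative
#' bioavailability. All other parameters are returned at their typical
#' values.
#'
#' @param typical an [rpv_params()] object of typical values.
#' @param effects named list of individual effects: `eta_CL`,
#'   `eta_F_oral`, `eta_ka_slow`, `eta_F_im_fast` (defaults 0) and
#'   optionally `kappa`, a vector of per-occasion log-CL deviations.
#' @param occasion optional occasion index whose `kappa` is folded into
#'   `CL` (profiles usually receive `kappa` separately, per dose).
#' @param female,theta_female sex covariate passed to
#'   [fimfast_individual()].
#' @return An [rpv_params()] object of individual values.
#' @export
individual_params <- function(typical, effects = list(), occasion = NULL,
                              female = FALSE, theta_female = 0) {
  e <- function(nm) if (is.null(effects[[nm]])) 0 else effects[[nm]]
  kap <- 0
  if (!is.null(occasion)) {
    if (occasion < 1 || occasion > MAX_OCCASIONS) {
      stop("occasion must be in 1..", MAX_OCCASIONS, call. = FALSE)
    }
    if (!is.null(effects$kappa)) kap <- effects$kappa[occasion]
  }
  p <- unclass(typical)
  p$CL <- p$CL * exp(e("eta_CL") + kap)
  p$F_oral <- p$F_oral * exp(e("eta_F_oral"))
  p$ka_slow <- p$ka_slow * exp(e("eta_ka_slow"))
  p$F_im_fast <- fimfast_individual(p$F_im_fast, e("eta_F_im_fast"),
                                    female, theta_female)
  suppressWarnings(do.call(rpv_params, p))
}

#' Sample individual random effects for a virtual population
#'
#' Draws independent normal effects (diagonal covariance) on the scales
#' used by [individual_params()]: log-scale etas for `CL`, `F_oral`,
#' `ka_slow`, a logit-scale eta for `F_im_fast`, and a matrix of
#' per-occasion `kappa` deviations on `CL`.
#'
#' @param re an [rpv_re()] specification.
#' @param n number of subjects.
#' @param n_occasions number of IOV occasions to draw (default 6).
#' @return List with matrix `eta` (n x 4, named columns) and matrix
#'   `kappa` (n x n_occasions).
#' @export
sample_effects <- function(re, n, n_occasions = MAX_OCCASIONS) {
  eta <- cbind(eta_CL = stats::rnorm(n, 0, re$omega_CL),
               eta_F_oral = stats::rnorm(n, 0, re$omega_F_oral),
               eta_ka_slow = stats::rnorm(n, 0, re$omega_ka_slow),
               eta_F_im_fast = stats::rnorm(n, 0, re$omega_F_im_fast))
  kappa <- matrix(stats::rnorm(n * n_occasions, 0, re$omega_IOV_CL),
                  n, n_occasions)
  list(eta = eta, kappa = kappa)
}

#' Residual error variance of an observation
#'
#' Route-specific residual unexplained variability: additive for oral
#' records (`sigma_add_oral^2`) and proportional for IM records
#' (`(sigma_prop_im * pred)^2`).
#'
#' @param pred model-predicted concentration(s), ng/mL, >= 0.
#' @param route `"oral"` or `"im"` (scalar or vector).
#' @param re an [rpv_re()] specification.
#' @return Variance(s), (ng/mL)^2.
#' @export
residual_error_variance <- function(pred, route, re = rpv_re()) {
  if (any(pred < 0)) stop("predictions must be >= 0", call. = FALSE)
  if (any(!route %in% c("oral", "im"))) {
    stop("unknown route", call. = FALSE)
  }
  n <- max(length(pred), length(route))
  pred <- rep_len(pred, n)
  route <- rep_len(route, n)
  ifelse(route == "oral", re$sigma_add_oral^2, (re$sigma_prop_im * pred)^2)
}
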