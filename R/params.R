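#' Structural population PK parameters for rilpivirine
#'
#' Constructs the fixed-effect parameter set of the two-compartment model
#' with zero-order oral absorption and parallel fast/slow first-order
#' intramuscular depot absorption. Defaults are the final population
#' estimates of the model (oral and long-acting IM rilpivirine in adults
#' with HIV followed in routine care).
#'
#' Internal unit conventions: time in hours, amounts in mg (converted to
#' micrograms inside the profile functions), volumes in litres, so that
#' concentrations come out directly in ng/mL. One week is 168 h and one
#' year 8766 h.
#'
#' @param CL apparent clearance, L/h.
#' @param V3 apparent central volume of distribution, L.
#' @param Q apparent intercompartmental clearance, L/h.
#' @param V4 apparent peripheral volume of distribution, L.
#' @param ka_fast fast IM depot absorption rate constant, 1/h.
#' @param ka_slow slow IM depot absorption rate constant, 1/h.
#' @param F_im_fast fraction of an IM dose released through the fast
#'   depot pathway, in (0, 1); the remainder drains through the slow depot.
#' @param F_oral relative oral-to-IM bioavailability (IM taken as 100%
#'   bioavailable). Typical value in (0, 1]; individual values sampled
#'   with lognormal variability may exceed 1.
#' @param D_oral duration of the zero-order oral input, h (fixed at 4 h).
#'
#' @return An object of class `rpv_params` (a named list).
#' @examples
#' p <- rpv_params()
#' biphasic_half_lives(p)
#' @export
rpv_params <- function(CL = 6.74, V3 = 277, Q = 4.08, V4 = 839,
                       ka_fast = 0.00214, ka_slow = 0.000229,
                       F_im_fast = 0.276, F_oral = 0.654, D_oral = 4) {
  p <- list(CL = CL, V3 = V3, Q = Q, V4 = V4,
            ka_fast = ka_fast, ka_slow = ka_slow,
            F_im_fast = F_im_fast, F_oral = F_oral, D_oral = D_oral)
  validate_rpv_params(p)
  structure(p, class = "rpv_params")
}

validate_rpv_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("invalid parameter: all parameters must be finite scalars (",
         paste(names(p)[!num], collapse = ", "), ")", call. = FALSE)
  }
  pos <- c("CL", "V3", "Q", "V4", "ka_fast", "ka_slow", "F_oral", "D_oral")
  bad <- pos[vapply(pos, function(nm) p[[nm]] < 0, logical(1))]
  strict <- c("CL", "V3", "V4", "ka_fast", "ka_slow", "F_oral", "D_oral")
  bad <- union(bad, strict[vapply(strict, function(nm) p[[nm]] <= 0, logical(1))])
  if (length(bad)) {
    stop("invalid parameter: ", paste(bad, collapse = ", "),
         " must be strictly positive (Q may be zero)", call. = FALSE)
  }
  if (p$F_im_fast <= 0 || p$F_im_fast >= 1) {
    stop("invalid parameter: F_im_fast must lie in (0, 1)", call. = FALSE)
  }
  ke <- p$CL / p$V3
  if (!(p$ka_slow < p$ka_fast && p$ka_fast < ke)) {
    warning("flip-flop condition ka_slow < ka_fast < CL/V3 does not hold; ",
            "the terminal slope after IM dosing may not reflect ka_slow",
            call. = FALSE)
  }
  invisible(p)
}

#' @export
print.rpv_params <- function(x, ...) {
  cat("Two-compartment rilpivirine PK parameters\n")
  cat(sprintf("  CL   %8.4g L/h    V3 %8.4g L\n", x$CL, x$V3))
  cat(sprintf("  Q    %8.4g L/h    V4 %8.4g L\n", x$Q, x$V4))
  cat(sprintf("  ka_fast %.3g 1/h   ka_slow %.3g 1/h\n", x$ka_fast, x$ka_slow))
  cat(sprintf("  F_im_fast %.3g     F_oral %.3g     D_oral %g h\n",
              x$F_im_fast, x$F_oral, x$D_oral))
  invisible(x)
}

HOURS_PER_WEEK <- 168
HOURS_PER_YEAR <- 8766

#' Two-compartment disposition micro- and macro-constants
#'
#' Computes the elimination and distribution micro-constants and the
#' bi-exponential macro rate constants (eigenvalues of the disposition
#' system) from clearances and volumes: `k10 = CL/V3`, `k12 = Q/V3`,
#' `k21 = Q/V4`; `lambda1 > lambda2` are the roots of
#' `s^2 - (k10 + k12 + k21) s + k10 k21`.
#'
#' @param params an [rpv_params()] object.
#' @return A list with `k10`, `k12`, `k21`, `lambda1`, `lambda2` (1/h).
#' @export
disposition_constants <- function(params) {
  validate_rpv_params(params)
  k10 <- params$CL / params$V3
  k12 <- params$Q / params$V3
  k21 <- params$Q / params$V4
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  list(k10 = k10, k12 = k12, k21 = k21,
       lambda1 = (s + disc) / 2, lambda2 = (s - disc) / 2)
}

#' Biphasic (distribution and terminal) half-lives after oral dosing
#'
#' Half-lives of the two disposition phases, `ln 2 / lambda1` and
#' `ln 2 / lambda2`. These depend only on clearances and volumes, not on
#' bioavailability.
#'
#' @inheritParams disposition_constants
#' @return Named numeric vector `c(alpha = , beta = )` in hours.
#' @export
biphasic_half_lives <- function(params) {
  d <- disposition_constants(params)
  if (d$lambda2 <= 0) {
    stop("degenerate disposition: lambda2 = 0, no terminal phase", call. = FALSE)
  }
  c(alpha = log(2) / d$lambda1, beta = log(2) / d$lambda2)
}

#' Apparent terminal half-life of long-acting IM rilpivirine
#'
#' Under flip-flop kinetics the terminal plasma slope after IM injection is
#' governed by the slow absorption rate constant, so the apparent terminal
#' half-life is `ln 2 / ka_slow`, reported in weeks (168 h/week).
#'
#' @param ka_slow slow depot absorption rate constant, 1/h.
#' @param params optional [rpv_params()] object used to verify the
#'   flip-flop condition (`ka_slow` below the disposition eigenvalues);
#'   a warning is issued when it fails and the value is still returned.
#' @return Half-life in weeks.
#' @export
terminal_half_life_im <- function(ka_slow, params = NULL) {
  if (!is.numeric(ka_slow) || length(ka_slow) != 1L || ka_slow <= 0) {
    stop("ka_slow must be a positive scalar", call. = FALSE)
  }
  if (!is.null(params)) {
    d <- disposition_constants(params)
    if (ka_slow >= min(d$lambda2, d$k10)) {
      warning("no flip-flop: ka_slow is not below the elimination rate ",
              "constants; returning ln2/ka_slow anyway", call. = FALSE)
    }
  }
  log(2) / ka_slow / HOURS_PER_WEEK
}

#' Time to reach steady state under long-acting IM dosing
#'
#' Conventional multiple of the apparent terminal half-life (default 5
#' half-lives, i.e. ~97% of steady state), converted to years at 8766
#' h/year.
#'
#' @inheritParams terminal_half_life_im
#' @param n_half_lives number of terminal half-lives defining "steady
#'   state" (default 5).
#' @return Time in years.
#' @export
time_to_steady_state <- function(ka_slow, n_half_lives = 5) {
  if (!is.numeric(ka_slow) || length(ka_slow) != 1L || ka_slow <= 0) {
    stop("ka_slow must be a positive scalar", call. = FALSE)
  }
  n_half_lives * log(2) / ka_slow / HOURS_PER_YEAR
}

#' Population interval of the individual IM terminal half-life
#'
#' With lognormal between-subject variability on `ka_slow`, individual
#' terminal half-lives are lognormal about the typical value. Returns the
#' central interval (default 90%) of that distribution in weeks, using
#' `sigma = sqrt(log(1 + CV^2))`.
#'
#' @inheritParams terminal_half_life_im
#' @param cv_percent between-subject coefficient of variation of
#'   `ka_slow`, percent.
#' @param level interval probability (default 0.90).
#' @return Named vector `c(lower = , upper = )` in weeks.
#' @export
halflife_interval <- function(ka_slow, cv_percent, level = 0.90) {
  if (cv_percent < 0) stop("cv_percent must be >= 0", call. = FALSE)
  t_typ <- terminal_half_life_im(ka_slow)
  sigma <- omega_from_cv(cv_percent)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = t_typ * exp(-z * sigma), upper = t_typ * exp(z * sigma))
}
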