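#' Dose events and dosing regimens
#'
#' A regimen is a data frame of dose events with columns `time` (h since
#' first dose), `amount` (mg), `route` (`"oral"` or `"im"`), `duration`
#' (h of zero-order input; 0 for IM) and `occasion` (incremental index of
#' IM injections, capped at 6; `NA` for oral doses).
#'
#' @param time h since the first dose, >= 0.
#' @param amount dose in mg, > 0.
#' @param route `"oral"` or `"im"`.
#' @param duration zero-order input duration in h (oral only).
#' @param occasion IM injection occasion index (assigned automatically by
#'   [build_regimen()]).
#' @return One-row data frame.
#' @export
dose_event <- function(time, amount, route = c("oral", "im"),
                       duration = if (route[1] == "oral") 4 else 0,
                       occasion = NA_integer_) {
  route <- match.arg(route)
  if (time < 0) stop("dose time must be >= 0", call. = FALSE)
  if (amount <= 0) stop("dose amount must be > 0", call. = FALSE)
  if (route == "oral" && duration <= 0) {
    stop("oral doses need a positive zero-order duration", call. = FALSE)
  }
  data.frame(time = time, amount = amount, route = route,
             duration = duration, occasion = as.integer(occasion),
             stringsAsFactors = FALSE)
}

MAX_OCCASIONS <- 6L

#' Assign IM injection occasions
#'
#' Numbers IM doses incrementally within a regimen (or subject), capping
#' the index at 6 so that late injections share the sixth occasion.
#'
#' @param regimen a regimen data frame.
#' @return The regimen with the `occasion` column filled in.
#' @export
assign_occasions <- function(regimen) {
  im <- regimen$route == "im"
  occ <- rep(NA_integer_, nrow(regimen))
  occ[im] <- pmin(seq_len(sum(im)), MAX_OCCASIONS)
  regimen$occasion <- occ
  regimen
}

#' Build a study dosing regimen from a template
#'
#' Templates mirror the long-acting rilpivirine schedules: a 4-week oral
#' lead-in (25 mg once daily), then either 900 mg IM at weeks 4 and 8
#' followed by 900 mg every 8 weeks (`"q8w_900"`), or 600 mg IM every 4
#' weeks starting at week 4 (`"q4w_600"`). Injections are emitted up to
#' and including the horizon.
#'
#' @param template `"q8w_900"` or `"q4w_600"`.
#' @param horizon_weeks length of the dosing history, weeks.
#' @param oral_dose daily oral dose, mg.
#' @param lead_in_days length of the oral lead-in, days.
#' @param d_oral zero-order oral input duration, h.
#' @return A regimen data frame with occasions assigned.
#' @examples
#' r <- build_regimen("q8w_900", horizon_weeks = 48)
#' subset(r, route == "im")$time / 168  # injection weeks
#' @export
build_regimen <- function(template = c("q8w_900", "q4w_600"),
                          horizon_weeks = 48, oral_dose = 25,
                          lead_in_days = 28, d_oral = 4) {
  template <- match.arg(template)
  horizon_h <- horizon_weeks * HOURS_PER_WEEK
  oral_times <- seq(0, by = 24, length.out = lead_in_days)
  oral <- data.frame(time = oral_times, amount = oral_dose, route = "oral",
                     duration = d_oral, occasion = NA_integer_,
                     stringsAsFactors = FALSE)
  lead_h <- lead_in_days * 24
  if (template == "q8w_900") {
    # loading at weeks 4 and 8, then maintenance every 8 weeks
    im_times <- c(lead_h, lead_h + 4 * HOURS_PER_WEEK,
                  seq(lead_h + 12 * HOURS_PER_WEEK, by = 8 * HOURS_PER_WEEK,
                      length.out = 1000))
    im_amount <- 900
  } else {
    im_times <- seq(lead_h, by = 4 * HOURS_PER_WEEK, length.out = 1000)
    im_amount <- 600
  }
  im_times <- im_times[im_times <= horizon_h]
  im <- if (length(im_times)) {
    data.frame(time = im_times, amount = im_amount, route = "im",
               duration = 0, occasion = NA_integer_, stringsAsFactors = FALSE)
  } else {
    oral[0, ]
  }
  reg <- rbind(oral[oral$time <= horizon_h | seq_len(nrow(oral)) == 1, ], im)
  reg <- reg[order(reg$time), , drop = FALSE]
  rownames(reg) <- NULL
  assign_occasions(reg)
}

validate_regimen <- function(regimen) {
  req <- c("time", "amount", "route", "duration", "occasion")
  if (!all(req %in% names(regimen))) {
    stop("regimen must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(regimen) == 0) return(invisible(regimen))
  if (any(!regimen$route %in% c("oral", "im"))) {
    stop("unknown route: ",
         paste(unique(setdiff(regimen$route, c("oral", "im"))), collapse = ", "),
         call. = FALSE)
  }
  if (any(regimen$time < 0)) stop("dose times must be >= 0", call. = FALSE)
  if (any(regimen$amount <= 0)) stop("dose amounts must be > 0", call. = FALSE)
  if (is.unsorted(regimen$time)) {
    stop("regimen must be sorted by time", call. = FALSE)
  }
  invisible(regimen)
}
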