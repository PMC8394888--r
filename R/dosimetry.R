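#' Build the stepwise UV irradiation schedule
#'
#' Chronic UVA irradiation runs three sessions per week (Mon/Wed/Fri) with a
#' stepwise dose escalation in MED units: 1/3 MED per session in week 1
#' (1 MED/week), 2/3 MED in week 2 (2 MED/week), sessions of 1, 4/3 and
#' 5/3 MED in week 3 (4 MED/week), then 2 MED per session (6 MED/week) from
#' week 4 through `last_irradiation_week`. Weeks after `last_irradiation_week`
#' carry no sessions (observation only).
#'
#' The default `last_irradiation_week = 11` makes the default 12-week calendar
#' total exactly 55 MED; irradiating through week 12 instead gives 61 MED, and
#' both calendars are constructible through the parameter.
#'
#' @param med_mj_cm2 MED calibration in mJ/cm2 (default 300).
#' @param total_weeks length of the experiment in weeks (>= 3).
#' @param last_irradiation_week last week with sessions (3..total_weeks).
#' @return A `dose_schedule`: list with `med_mj_cm2`, `total_weeks`,
#'   `last_irradiation_week` and a data.frame `sessions` with columns
#'   `week`, `day_label`, `dose_med`, `dose_mj_cm2`.
#' @export
build_schedule <- function(med_mj_cm2 = 300, total_weeks = 12,
                           last_irradiation_week = 11) {
  if (med_mj_cm2 <= 0) stop("build_schedule: MED calibration must be positive")
  if (total_weeks < 3) stop("build_schedule: total_weeks must be >= 3")
  if (last_irradiation_week < 3 || last_irradiation_week > total_weeks)
    stop("build_schedule: last_irradiation_week must lie in [3, total_weeks]")
  days <- c("Mon", "Wed", "Fri")
  # session doses kept as integer thirds of a MED so weekly and cumulative
  # totals are exact rational arithmetic
  week_thirds <- function(w) {
    if (w == 1) rep(1L, 3)
    else if (w == 2) rep(2L, 3)
    else if (w == 3) c(3L, 4L, 5L)  # fixed Mon/Wed/Fri order
    else rep(6L, 3)
  }
  sess <- do.call(rbind, lapply(seq_len(last_irradiation_week), function(w) {
    data.frame(week = w, day_label = days, dose_thirds = week_thirds(w))
  }))
  sess$dose_med <- sess$dose_thirds / 3
  sess$dose_mj_cm2 <- sess$dose_med * med_mj_cm2
  structure(
    list(med_mj_cm2 = med_mj_cm2, total_weeks = total_weeks,
         last_irradiation_week = last_irradiation_week, sessions = sess),
    class = "dose_schedule")
}

#' @export
print.dose_schedule <- function(x, ...) {
  tot <- cumulative_dose(x)
  cat(sprintf(
    "<dose_schedule> %d weeks, irradiation through week %d, MED = %g mJ/cm2\n  total %g MED = %g mJ/cm2 over %d sessions\n",
    x$total_weeks, x$last_irradiation_week, x$med_mj_cm2,
    tot$dose_med, tot$dose_mj_cm2, nrow(x$sessions)))
  invisible(x)
}

#' Cumulative UV dose
#'
#' Sums session doses through a given week (all sessions when
#' `through_week = NULL`).
#'
#' @param schedule a [build_schedule()] result.
#' @param through_week last week to include, or `NULL` for the whole schedule.
#' @return list with `dose_med` and `dose_mj_cm2`.
#' @export
cumulative_dose <- function(schedule, through_week = NULL) {
  stopifnot(inherits(schedule, "dose_schedule"))
  if (is.null(through_week)) through_week <- schedule$total_weeks
  if (through_week < 0 || through_week > schedule$total_weeks)
    stop("cumulative_dose: through_week outside the schedule span")
  keep <- schedule$sessions$week <= through_week
  med <- sum(schedule$sessions$dose_thirds[keep]) / 3
  list(dose_med = med, dose_mj_cm2 = med * schedule$med_mj_cm2)
}

#' Weekly dose totals
#'
#' @param schedule a [build_schedule()] result.
#' @return data.frame with `week` and `dose_med` (weeks without sessions
#'   included with 0).
#' @export
weekly_dose <- function(schedule) {
  stopifnot(inherits(schedule, "dose_schedule"))
  weeks <- seq_len(schedule$total_weeks)
  med <- vapply(weeks, function(w)
    sum(schedule$sessions$dose_thirds[schedule$sessions$week == w]) / 3, numeric(1))
  data.frame(week = weeks, dose_med = med,
             dose_mj_cm2 = med * schedule$med_mj_cm2)
}

#' Exposure time for a dose at a given irradiance
#'
#' time (s) = dose (mJ/cm2) / irradiance (mW/cm2). Note 150 W/m2 = 15 mW/cm2.
#'
#' @param dose_mj_cm2 dose in mJ/cm2 (>= 0).
#' @param irradiance_mw_cm2 irradiance in mW/cm2 (> 0).
#' @return exposure time in seconds.
#' @export
exposure_time <- function(dose_mj_cm2, irradiance_mw_cm2) {
  if (any(irradiance_mw_cm2 <= 0))
    stop("exposure_time: irradiance must be positive")
  if (any(dose_mj_cm2 < 0)) stop("exposure_time: dose must be non-negative")
  dose_mj_cm2 / irradiance_mw_cm2
}

#' Export a schedule to CSV
#'
#' Columns `week,day,dose_med,dose_mj_cm2`.
#'
#' @param schedule a [build_schedule()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "dose_schedule"))
  out <- schedule$sessions[, c("week", "day_label", "dose_med", "dose_mj_cm2")]
  names(out)[names(out) == "day_label"] <- "day"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
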