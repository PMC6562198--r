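#' Restrict laboratory results to an admission's attachment window
#'
#' A laboratory result belongs to an admission if it was received by the
#' laboratory between the start of the day before admission and the end of
#' the day of discharge (local calendar midnights). The day-before extension
#' captures samples taken in the emergency department for patients admitted
#' overnight.
#'
#' @param labs Laboratory results (columns `admission_id`, `received_time`,
#'   `analyte`, `value`).
#' @param admissions Admissions table (columns `admission_id`, `admit_time`,
#'   `discharge_time`).
#' @return The retained rows of `labs`, as a tibble.
#' @export
attach_admission_labs <- function(labs, admissions) {
  joined <- left_join(as_tibble(labs),
                      select(admissions, "admission_id", "admit_time",
                             "discharge_time"),
                      by = "admission_id")
  lower <- floor_date(joined$admit_time, "day") - 86400
  upper <- floor_date(joined$discharge_time, "day") + 86400  # exclusive
  keep <- !is.na(joined$admit_time) &
    joined$received_time >= lower & joined$received_time < upper
  out <- as_tibble(labs)[keep, , drop = FALSE]
  out
}

#' Link each vital-sign set to the most recent laboratory results
#'
#' For every observation row, carries forward the latest result of each of
#' the seven analytes received at or before the observation time, subject to
#' an ageing horizon: results older than `horizon_hours` are treated as
#' absent, both for scoring and for `time_since_labs`. Results received
#' strictly after the observation time are never used; a result received at
#' exactly the observation time counts with age 0.
#'
#' `time_since_labs` is the age in hours of the most recently received
#' result among the linked analytes -- the minimum of the per-analyte ages --
#' or `horizon_hours` when no analyte is available.
#'
#' @param vitals Vital-sign observation sets (must include `admission_id`
#'   and `obs_time`).
#' @param labs Laboratory results; if `admissions` is supplied they are
#'   first restricted to each admission's attachment window via
#'   [attach_admission_labs()].
#' @param admissions Optional admissions table (see above).
#' @param horizon_hours Carry-forward horizon in hours (default 120, i.e. 5
#'   days).
#' @return `vitals` as a tibble with, per analyte, `<analyte>_value` and
#'   `<analyte>_age_hours` columns (NA = absent), plus `time_since_labs`.
#' @export
link_labs <- function(vitals, labs, admissions = NULL, horizon_hours = 120) {
  stopifnot(horizon_hours > 0)
  if (!is.null(admissions)) {
    labs <- attach_admission_labs(labs, admissions)
  }
  out <- as_tibble(vitals)
  key <- select(out, "admission_id", "obs_time")
  for (an in ldtews_analytes()) {
    la <- labs[labs$analyte == an, c("admission_id", "received_time", "value")]
    # a single row per (admission, received_time): later rows win on ties
    la <- la[order(la$admission_id, la$received_time), , drop = FALSE]
    dup <- duplicated(la[c("admission_id", "received_time")],
                      fromLast = TRUE)
    la <- la[!dup, , drop = FALSE]
    j <- left_join(key, la,
                   by = join_by(admission_id,
                                closest(obs_time >= received_time)))
    age <- as.numeric(difftime(j$obs_time, j$received_time, units = "hours"))
    stale <- !is.na(age) & age > horizon_hours
    val <- j$value
    val[stale] <- NA_real_
    age[stale] <- NA_real_
    out[[paste0(an, "_value")]] <- val
    out[[paste0(an, "_age_hours")]] <- age
  }
  out$time_since_labs <- time_since_labs(out, horizon_hours = horizon_hours)
  out
}

#' Time since the most recent linked laboratory result
#'
#' @param linked A linked observation table with `<analyte>_age_hours`
#'   columns (as produced by [link_labs()]).
#' @param horizon_hours Value returned when every analyte slot is absent.
#' @return Numeric vector of hours in `[0, horizon_hours]`.
#' @export
time_since_labs <- function(linked, horizon_hours = 120) {
  age_cols <- paste0(ldtews_analytes(), "_age_hours")
  present <- intersect(age_cols, names(linked))
  if (length(present) == 0) {
    abort("time_since_labs(): no <analyte>_age_hours columns found")
  }
  ages <- as.data.frame(linked[present])
  tsl <- do.call(pmin, c(ages, list(na.rm = TRUE)))
  tsl[is.na(tsl)] <- horizon_hours
  pmin(tsl, horizon_hours)
}
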