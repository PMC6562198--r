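#' Cohort construction settings
#'
#' @param min_age Minimum age in whole years (adults: 16).
#' @param qualifying_specialties Specialty codes counting as the higher-risk
#'   medical specialties eligible for the cohort.
#' @param outcome_horizon_hours Outcome look-ahead from each observation set
#'   (24 h).
#' @param end_of_life_lookback_hours Exclusion (b) window: admissions with
#'   no vital signs recorded in this many hours before the earliest of ICU
#'   admission, discharge or death are excluded, as a proxy for end-of-life
#'   pathways.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(min_age = 16,
                          qualifying_specialties = "acute_medicine",
                          outcome_horizon_hours = 24,
                          end_of_life_lookback_hours = 24) {
  stopifnot(min_age > 0, outcome_horizon_hours > 0,
            end_of_life_lookback_hours > 0,
            length(qualifying_specialties) >= 1)
  structure(list(min_age = min_age,
                 qualifying_specialties = qualifying_specialties,
                 outcome_horizon_hours = outcome_horizon_hours,
                 end_of_life_lookback_hours = end_of_life_lookback_hours),
            class = "cohort_config")
}

flow_row <- function(step, excluded, remaining) {
  tibble(step = step, excluded_n = excluded, remaining_n = remaining)
}

#' Apply cohort inclusion criteria
#'
#' Keeps emergency admissions of patients aged at least `min_age` to a
#' qualifying specialty with at least one complete vital-sign observation
#' set. Exclusion counts are attributed to the first failing criterion, in
#' the order age, admission method, specialty, vital signs, so the audit
#' trail sums: input n = retained n + per-step exclusions.
#'
#' @param admissions Admissions table.
#' @param vitals Complete vital-sign sets (as returned by [read_vitals()],
#'   which drops incomplete sets).
#' @param config A [cohort_config()].
#' @return A list with `admissions` (the retained rows, as a tibble) and
#'   `flow` (a tibble of per-step counts, the flow-diagram analogue).
#' @export
apply_inclusion <- function(admissions, vitals,
                            config = cohort_config()) {
  adm <- as_tibble(admissions)
  flow <- flow_row("considered", 0L, nrow(adm))
  steps <- list(
    age = adm$age >= config$min_age,
    `admission method` = adm$admission_method == "emergency",
    specialty = adm$specialty %in% config$qualifying_specialties,
    `no complete vital signs` =
      adm$admission_id %in% unique(vitals$admission_id)
  )
  keep <- rep(TRUE, nrow(adm))
  for (nm in names(steps)) {
    fail <- keep & !steps[[nm]]
    keep <- keep & steps[[nm]]
    flow <- bind_rows(flow, flow_row(nm, sum(fail), sum(keep)))
  }
  list(admissions = adm[keep, , drop = FALSE], flow = flow)
}

#' Apply cohort exclusion criteria
#'
#' Drops (a) admissions discharged alive before the first midnight after
#' admission, and (b) admissions with no vital-sign set recorded in the
#' `end_of_life_lookback_hours` before the earliest of first ICU admission,
#' discharge or death (a proxy for end-of-life pathways). Attribution is to
#' the first failing criterion, (a) before (b).
#'
#' @inheritParams apply_inclusion
#' @return A list with `admissions` and `flow` as in [apply_inclusion()].
#' @export
apply_exclusions <- function(admissions, vitals,
                             config = cohort_config()) {
  adm <- as_tibble(admissions)
  first_midnight <- floor_date(adm$admit_time, "day") + 86400
  excl_a <- !adm$death_in_hospital & adm$discharge_time < first_midnight

  event_time <- pmin(adm$death_time, adm$icu_admission_time,
                     adm$discharge_time, na.rm = TRUE)
  lb <- config$end_of_life_lookback_hours * 3600
  vt <- as_tibble(vitals)[, c("admission_id", "obs_time")]
  vt <- left_join(vt,
                  tibble(admission_id = adm$admission_id,
                         .event_time = event_time),
                  by = "admission_id")
  recent <- vt$obs_time >= vt$.event_time - lb & vt$obs_time <= vt$.event_time
  has_recent <- adm$admission_id %in%
    unique(vt$admission_id[!is.na(recent) & recent])
  excl_b <- !excl_a & !has_recent

  keep <- !excl_a & !excl_b
  flow <- bind_rows(
    flow_row("discharged alive before first midnight", sum(excl_a),
             nrow(adm) - sum(excl_a)),
    flow_row("no vital signs before first event (end-of-life proxy)",
             sum(excl_b), sum(keep))
  )
  list(admissions = adm[keep, , drop = FALSE], flow = flow)
}

#' Build the analysis cohort
#'
#' Runs [apply_inclusion()] then [apply_exclusions()] and concatenates
#' their audit flows.
#'
#' @inheritParams apply_inclusion
#' @return A list with `admissions` and the combined `flow` tibble.
#' @export
build_cohort <- function(admissions, vitals, config = cohort_config()) {
  inc <- apply_inclusion(admissions, vitals, config)
  exc <- apply_exclusions(inc$admissions, vitals, config)
  list(admissions = exc$admissions,
       flow = bind_rows(inc$flow, exc$flow))
}

#' Label observation sets with 24-hour outcomes
#'
#' For every observation row, labels whether the first of in-hospital death
#' or unanticipated ICU admission occurs within the outcome horizon after
#' the observation time, together with each event separately. The window is
#' half-open: an event at exactly `obs_time + horizon` counts as positive.
#' Observation sets recorded at or after the first event time are dropped
#' (the patient is no longer at risk on a ward).
#'
#' @param data Observation-level table with `admission_id` and `obs_time`
#'   (e.g. scored linked observations).
#' @param admissions Admissions table with `death_time` and
#'   `icu_admission_time`.
#' @param config A [cohort_config()] (supplies the horizon).
#' @return `data` (post-event rows removed) as a tibble with logical columns
#'   `outcome_primary_24h`, `outcome_death_24h`, `outcome_icu_24h`.
#' @export
label_outcomes <- function(data, admissions, config = cohort_config()) {
  out <- as_tibble(data)
  adm <- select(as_tibble(admissions), "admission_id", "death_time",
                "icu_admission_time")
  out <- left_join(out, adm, by = "admission_id")
  first_event <- pmin(out$death_time, out$icu_admission_time, na.rm = TRUE)
  pre_event <- is.na(first_event) | out$obs_time < first_event
  out <- out[pre_event, , drop = FALSE]
  h <- config$outcome_horizon_hours * 3600
  in_window <- function(ev, obs) {
    !is.na(ev) & ev > obs & ev <= obs + h
  }
  out$outcome_death_24h <- in_window(out$death_time, out$obs_time)
  out$outcome_icu_24h <- in_window(out$icu_admission_time, out$obs_time)
  out$outcome_primary_24h <- out$outcome_death_24h | out$outcome_icu_24h
  out$death_time <- NULL
  out$icu_admission_time <- NULL
  out
}
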