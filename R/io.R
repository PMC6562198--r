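time_format <- "%Y-%m-%dT%H:%M:%S"

parse_time <- function(x) {
  as.POSIXct(x, format = time_format, tz = "UTC")
}

format_time <- function(t) {
  out <- format(t, time_format, tz = "UTC")
  out[is.na(t)] <- ""
  out
}

require_columns <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing required column(s): %s", what,
                  paste(missing_cols, collapse = ", ")))
  }
}

report_rejects <- function(bad, what, reason) {
  if (any(bad)) {
    rows <- which(bad)
    shown <- paste(head(rows, 10), collapse = ", ")
    if (length(rows) > 10) shown <- paste0(shown, ", ...")
    warn(sprintf("%s: rejected %d row(s) (%s): data rows %s", what,
                 sum(bad), reason, shown))
  }
  bad
}

#' Read an admissions table
#'
#' Reads the delimited admissions schema: columns `admission_id`, `age`,
#' `sex` (`male`/`female`), `admit_time`, `discharge_time` (ISO-8601,
#' e.g. `2023-04-01T13:05:00`), `admission_method`
#' (`emergency`/`elective`), `specialty`, `death_time` and
#' `icu_admission_time` (blank when absent). `death_in_hospital` is derived
#' from the presence of `death_time`. Schema violations (missing columns,
#' unparseable mandatory timestamps, unknown categorical tokens) fail hard;
#' use the writer [write_admissions()] for a bit-faithful round trip.
#'
#' @param path CSV file path.
#' @return Admissions tibble.
#' @export
read_admissions <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  require_columns(raw, c("admission_id", "age", "sex", "admit_time",
                         "discharge_time", "admission_method", "specialty",
                         "death_time", "icu_admission_time"),
                  "admissions")
  parse_opt <- function(x) parse_time(ifelse(is.na(x) | x == "", NA, x))
  out <- tibble(
    admission_id = raw$admission_id,
    age = as.integer(raw$age),
    sex = raw$sex,
    admit_time = parse_time(raw$admit_time),
    discharge_time = parse_time(raw$discharge_time),
    admission_method = raw$admission_method,
    specialty = raw$specialty,
    death_time = parse_opt(raw$death_time),
    icu_admission_time = parse_opt(raw$icu_admission_time)
  )
  if (anyNA(out$admit_time) || anyNA(out$discharge_time)) {
    abort("admissions: unparseable admit_time/discharge_time")
  }
  if (!all(out$sex %in% c("male", "female"))) {
    abort("admissions: sex must be 'male' or 'female'")
  }
  if (!all(out$admission_method %in% c("emergency", "elective"))) {
    abort("admissions: admission_method must be 'emergency' or 'elective'")
  }
  if (any(out$discharge_time < out$admit_time)) {
    abort("admissions: discharge_time precedes admit_time")
  }
  out$death_in_hospital <- !is.na(out$death_time)
  select(out, "admission_id", "age", "sex", "admit_time", "discharge_time",
         "admission_method", "specialty", "death_in_hospital", "death_time",
         "icu_admission_time")
}

#' Read a vital-sign observation table
#'
#' Reads the vitals schema: `admission_id`, `obs_time`, `heart_rate`,
#' `systolic_bp`, `respiratory_rate`, `temperature`, `spo2`,
#' `supplemental_oxygen` (`true`/`false`) and `consciousness` (an AVPU
#' level `A`/`V`/`P`/`U`, or a GCS total 3--15 which is converted via
#' [gcs_to_avpu()]). Rows with any of the seven inputs missing or outside
#' the plausibility bounds of the scoring table are rejected with a warning
#' naming the rows -- an incomplete set cannot yield a NEWS aggregate. The
#' count of rejected rows is attached as attribute `n_rejected`.
#'
#' @param path CSV file path.
#' @param table Scoring table supplying plausibility bounds and the
#'   GCS-to-AVPU mapping.
#' @return Vitals tibble with `avpu` and `gcs` columns.
#' @export
read_vitals <- function(path, table = default_scoring_table()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  require_columns(raw, c("admission_id", "obs_time", "heart_rate",
                         "systolic_bp", "respiratory_rate", "temperature",
                         "spo2", "supplemental_oxygen", "consciousness"),
                  "vitals")
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- tibble(
    admission_id = raw$admission_id,
    obs_time = parse_time(raw$obs_time),
    heart_rate = num(raw$heart_rate),
    systolic_bp = num(raw$systolic_bp),
    respiratory_rate = num(raw$respiratory_rate),
    temperature = num(raw$temperature),
    spo2 = num(raw$spo2)
  )
  ox <- tolower(raw$supplemental_oxygen)
  out$supplemental_oxygen <- ifelse(ox %in% c("true", "1", "yes"), TRUE,
                                    ifelse(ox %in% c("false", "0", "no"),
                                           FALSE, NA))
  cons <- raw$consciousness
  is_avpu <- cons %in% c("A", "V", "P", "U")
  gcs <- suppressWarnings(as.numeric(ifelse(is_avpu, NA, cons)))
  valid_gcs <- !is.na(gcs) & gcs >= 3 & gcs <= 15 & gcs == round(gcs)
  avpu <- ifelse(is_avpu, cons, NA_character_)
  avpu[valid_gcs] <- gcs_to_avpu(gcs[valid_gcs],
                                 mapping = table$gcs_to_avpu)
  out$avpu <- avpu
  out$gcs <- ifelse(valid_gcs, gcs, NA_real_)

  incomplete <- is.na(out$obs_time) | is.na(out$heart_rate) |
    is.na(out$systolic_bp) | is.na(out$respiratory_rate) |
    is.na(out$temperature) | is.na(out$spo2) |
    is.na(out$supplemental_oxygen) | is.na(out$avpu)
  report_rejects(incomplete, "vitals", "incomplete observation set")

  pl <- table$plausibility
  implausible <- !incomplete & (
    out$heart_rate < pl$heart_rate[1] | out$heart_rate > pl$heart_rate[2] |
    out$systolic_bp < pl$systolic_bp[1] |
      out$systolic_bp > pl$systolic_bp[2] |
    out$respiratory_rate < pl$respiratory_rate[1] |
      out$respiratory_rate > pl$respiratory_rate[2] |
    out$temperature < pl$temperature[1] |
      out$temperature > pl$temperature[2] |
    out$spo2 < pl$spo2[1] | out$spo2 > pl$spo2[2])
  report_rejects(implausible, "vitals", "implausible value")

  res <- out[!incomplete & !implausible, , drop = FALSE]
  attr(res, "n_rejected") <- sum(incomplete | implausible)
  res
}

#' Read a laboratory results table
#'
#' Reads the long-format labs schema: `admission_id`, `received_time`
#' (ISO-8601, the time the specimen was received by the laboratory),
#' `analyte` (one of [ldtews_analytes()]) and `value` (positive real).
#' An unknown analyte token is a schema error; rows with missing or
#' non-positive values are rejected with a warning.
#'
#' @param path CSV file path.
#' @return Labs tibble.
#' @export
read_labs <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  require_columns(raw, c("admission_id", "received_time", "analyte",
                         "value"), "labs")
  unknown <- setdiff(unique(raw$analyte), ldtews_analytes())
  if (length(unknown) > 0) {
    abort(sprintf("labs: unknown analyte token(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  out <- tibble(
    admission_id = raw$admission_id,
    received_time = parse_time(raw$received_time),
    analyte = raw$analyte,
    value = suppressWarnings(as.numeric(raw$value))
  )
  bad <- is.na(out$received_time) | is.na(out$value) | out$value <= 0
  report_rejects(bad, "labs", "missing/unparseable time or non-positive value")
  res <- out[!bad, , drop = FALSE]
  attr(res, "n_rejected") <- sum(bad)
  res
}

#' @rdname read_admissions
#' @param admissions,path Admissions tibble and destination path.
#' @export
write_admissions <- function(admissions, path) {
  out <- tibble(
    admission_id = admissions$admission_id,
    age = admissions$age,
    sex = admissions$sex,
    admit_time = format_time(admissions$admit_time),
    discharge_time = format_time(admissions$discharge_time),
    admission_method = admissions$admission_method,
    specialty = admissions$specialty,
    death_time = format_time(admissions$death_time),
    icu_admission_time = format_time(admissions$icu_admission_time)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname read_vitals
#' @param vitals,path Vitals tibble and destination path.
#' @export
write_vitals <- function(vitals, path) {
  consciousness <- ifelse(!is.na(vitals$gcs),
                          format(vitals$gcs, trim = TRUE),
                          vitals$avpu)
  out <- tibble(
    admission_id = vitals$admission_id,
    obs_time = format_time(vitals$obs_time),
    heart_rate = vitals$heart_rate,
    systolic_bp = vitals$systolic_bp,
    respiratory_rate = vitals$respiratory_rate,
    temperature = sprintf("%.1f", vitals$temperature),
    spo2 = vitals$spo2,
    supplemental_oxygen = ifelse(vitals$supplemental_oxygen, "true",
                                 "false"),
    consciousness = consciousness
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname read_labs
#' @param labs,path Labs tibble and destination path.
#' @export
write_labs <- function(labs, path) {
  out <- tibble(
    admission_id = labs$admission_id,
    received_time = format_time(labs$received_time),
    analyte = labs$analyte,
    value = labs$value
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes cohort construction, laboratory linkage, scoring, optional
#' decay-coefficient fitting, risk-index computation and discrimination
#' evaluation in one call, returning every intermediate table plus a
#' machine-readable manifest. Any stage failure is rethrown with the stage
#' name. With `beta = NULL` the coefficient is fitted by [fit_beta()];
#' supplying a value (e.g. the development-phase 0.26) disables fitting and
#' runs an evaluation-only pipeline.
#'
#' @param admissions,vitals,labs Input tibbles (from the readers or
#'   [simulate_cohort()]) or CSV file paths.
#' @param beta Decay coefficient, or `NULL` to fit it.
#' @param seed Seed used for fold assignment when fitting; recorded in the
#'   manifest.
#' @param config A [cohort_config()].
#' @param scoring_table An `ews_scoring_table`.
#' @param horizon_hours Carry-forward/decay horizon.
#' @param fit_grid,n_folds Grid and folds passed to [fit_beta()].
#' @param out_dir Optional directory; when given, all result tables are
#'   written as CSV and the manifest as YAML.
#' @return A list with `cohort_flow`, `scored` (the labelled scored
#'   observation table), `fit` (NULL when `beta` supplied), `beta`,
#'   `evaluation` and `manifest`.
#' @export
run_pipeline <- function(admissions, vitals, labs, beta = NULL, seed = 1,
                         config = cohort_config(),
                         scoring_table = default_scoring_table(),
                         horizon_hours = 120,
                         fit_grid = seq(0.01, 0.99, by = 0.01),
                         n_folds = 10, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  if (is.character(admissions)) {
    admissions <- stage("read", read_admissions(admissions))
  }
  if (is.character(vitals)) {
    vitals <- stage("read", read_vitals(vitals, table = scoring_table))
  }
  if (is.character(labs)) labs <- stage("read", read_labs(labs))

  cohort <- stage("cohort", build_cohort(admissions, vitals, config))
  vit <- vitals[vitals$admission_id %in% cohort$admissions$admission_id, ,
                drop = FALSE]
  linked <- stage("link",
                  link_labs(vit, labs, admissions = cohort$admissions,
                            horizon_hours = horizon_hours))
  scored <- stage("score", {
    s <- score_ldtews(score_news(linked, table = scoring_table),
                      admissions = cohort$admissions, table = scoring_table)
    label_outcomes(s, cohort$admissions, config)
  })
  fit <- NULL
  if (is.null(beta)) {
    fit <- stage("fit", fit_beta(scored, grid = fit_grid,
                                 n_folds = n_folds, seed = seed,
                                 horizon_hours = horizon_hours))
    beta <- fit$beta
  }
  scored <- stage("score", add_risk_index(scored, beta = beta,
                                          horizon_hours = horizon_hours))
  evaluation <- stage("evaluate", evaluate_scores(scored))

  manifest <- list(
    package = "ldtnews",
    version = as.character(utils::packageVersion("ldtnews")),
    seed = seed,
    beta = beta,
    beta_fitted = !is.null(fit),
    horizon_hours = horizon_hours,
    n_admissions_in = nrow(admissions),
    n_admissions_cohort = nrow(cohort$admissions),
    n_observations = nrow(scored),
    config_hash = rlang::hash(list(config = unclass(config),
                                   horizon_hours = horizon_hours,
                                   fit_grid = fit_grid, n_folds = n_folds,
                                   beta_input = beta,
                                   seed = seed))
  )
  bundle <- list(cohort_flow = cohort$flow, scored = scored, fit = fit,
                 beta = beta, evaluation = evaluation, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(cohort$flow, file.path(out_dir, "cohort_flow.csv"))
    scored_out <- mutate(scored,
                         obs_time = format_time(.data$obs_time))
    readr::write_csv(scored_out, file.path(out_dir, "scored.csv"))
    if (!is.null(fit)) {
      readr::write_csv(fit$curve, file.path(out_dir, "beta_curve.csv"))
    }
    readr::write_csv(evaluation, file.path(out_dir, "evaluation.csv"))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  bundle
}
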