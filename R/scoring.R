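#' Convert Glasgow Coma Scale values to the AVPU scale
#'
#' NEWS scores consciousness on the four-level AVPU scale (Alert, responds
#' to Voice, responds to Pain, Unresponsive). Where an observation set
#' records a GCS instead, it is converted with a configurable mapping; the
#' default is 15 -> A, 13--14 -> V, 9--12 -> P, 3--8 -> U.
#'
#' @param gcs Integer vector of GCS totals in 3--15 (NAs pass through).
#' @param mapping Named list of inclusive integer ranges per AVPU level, as
#'   in the `gcs_to_avpu` block of the scoring-table YAML. Defaults to the
#'   shipped mapping.
#' @return Character vector of AVPU levels (`"A"`, `"V"`, `"P"`, `"U"`).
#' @export
#' @examples
#' gcs_to_avpu(c(15, 13, 9, 3))
gcs_to_avpu <- function(gcs, mapping = NULL) {
  mapping <- mapping %||% default_scoring_table()$gcs_to_avpu
  bad <- !is.na(gcs) & (gcs < 3 | gcs > 15 | gcs != round(gcs))
  if (any(bad)) {
    abort(sprintf("GCS values must be integers in [3, 15]; got %s",
                  paste(unique(gcs[bad]), collapse = ", ")))
  }
  out <- rep(NA_character_, length(gcs))
  for (level in names(mapping)) {
    rng <- mapping[[level]]
    out[!is.na(gcs) & gcs >= rng[1] & gcs <= rng[2]] <- level
  }
  out
}

#' Weight of a single NEWS component
#'
#' Looks one vital-sign value up in the scoring table's bands. Numeric bands
#' are half-open `[lower, upper)`; `supplemental_oxygen` takes a logical;
#' `consciousness` takes an AVPU level.
#'
#' @param component One of `"respiratory_rate"`, `"spo2"`,
#'   `"supplemental_oxygen"`, `"temperature"`, `"systolic_bp"`,
#'   `"heart_rate"`, `"consciousness"`.
#' @param value Vector of measured values (logical for oxygen, AVPU
#'   character for consciousness, numeric otherwise).
#' @param table An `ews_scoring_table`.
#' @return Integer weights (0--3; 0/2 for oxygen).
#' @export
#' @examples
#' news_component_weight("heart_rate", 75)
#' news_component_weight("consciousness", "V")
news_component_weight <- function(component, value,
                                  table = default_scoring_table()) {
  comp <- table$news$components[[component]]
  if (is.null(comp)) {
    abort(sprintf("unknown NEWS component '%s'", component))
  }
  switch(comp$kind,
    numeric = band_weight(as.numeric(value), comp$bands),
    binary = ifelse(as.logical(value), comp$weight_true, comp$weight_false),
    categorical = {
      w <- comp$weights[as.character(value)]
      if (anyNA(w) && !anyNA(value)) {
        abort("consciousness values must be AVPU levels A/V/P/U")
      }
      unname(w)
    }
  )
}

#' Aggregate NEWS over a table of vital-sign observation sets
#'
#' Computes the aggregate National Early Warning Score for every row of a
#' data frame of complete observation sets. Temperature is banded at 0.1
#' degC resolution; other inputs are banded as recorded. Rows with any of
#' the seven inputs missing raise an error -- incomplete sets are expected
#' to be filtered at read time (see [read_vitals()]).
#'
#' @param data Data frame with columns `heart_rate`, `systolic_bp`,
#'   `respiratory_rate`, `temperature`, `spo2`, `supplemental_oxygen`
#'   (logical) and `avpu` (AVPU level).
#' @param table An `ews_scoring_table`.
#' @param keep_components Also keep per-component weight columns
#'   (`news_heart_rate`, ...)?
#' @return The input as a tibble with an integer `news` column appended
#'   (0 to the table's declared maximum, 20 by default).
#' @export
#' @examples
#' vitals <- tibble::tibble(
#'   heart_rate = c(75, 135), systolic_bp = c(120, 88),
#'   respiratory_rate = c(16, 26), temperature = c(36.8, 35.0),
#'   spo2 = c(98, 91), supplemental_oxygen = c(FALSE, TRUE),
#'   avpu = c("A", "V")
#' )
#' score_news(vitals)$news
score_news <- function(data, table = default_scoring_table(),
                       keep_components = FALSE) {
  needed <- c("heart_rate", "systolic_bp", "respiratory_rate", "temperature",
              "spo2", "supplemental_oxygen", "avpu")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("score_news(): missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  incomplete <- Reduce(`|`, lapply(data[needed], is.na))
  if (any(incomplete)) {
    abort(sprintf(
      "score_news(): %d row(s) have incomplete vital-sign sets; %s",
      sum(incomplete), "filter incomplete sets before scoring"))
  }
  out <- as_tibble(data)
  values <- list(
    respiratory_rate = out$respiratory_rate,
    spo2 = out$spo2,
    supplemental_oxygen = out$supplemental_oxygen,
    temperature = round(out$temperature, 1),
    systolic_bp = out$systolic_bp,
    heart_rate = out$heart_rate,
    consciousness = out$avpu
  )
  weights <- lapply(names(values), function(nm) {
    news_component_weight(nm, values[[nm]], table)
  })
  names(weights) <- names(values)
  if (keep_components) {
    for (nm in names(weights)) out[[paste0("news_", nm)]] <- weights[[nm]]
  }
  out$news <- as.integer(Reduce(`+`, weights))
  out
}

#' Weight of a single LDT-EWS analyte
#'
#' Looks a laboratory value up in the analyte's bands (sex-specific bands
#' where the table distinguishes males and females). A missing value scores
#' zero: an analyte never measured, or aged past the carry-forward horizon,
#' contributes nothing to the aggregate.
#'
#' @param analyte One of [ldtews_analytes()].
#' @param value Numeric vector; `NA` means absent.
#' @param sex `"male"`/`"female"`, required (and recycled) only for
#'   sex-specific analytes.
#' @param table An `ews_scoring_table`.
#' @return Integer weights.
#' @export
#' @examples
#' ldtews_component_weight("albumin", c(40, 20, NA))
#' ldtews_component_weight("haemoglobin", 110, sex = c("male", "female"))
ldtews_component_weight <- function(analyte, value, sex = NULL,
                                    table = default_scoring_table()) {
  comp <- table$ldtews$components[[analyte]]
  if (is.null(comp)) {
    abort(sprintf("unknown LDT-EWS analyte '%s'", analyte))
  }
  value <- as.numeric(value)
  if (isTRUE(comp$sex_specific)) {
    if (is.null(sex)) {
      abort(sprintf("analyte '%s' has sex-specific cut-offs; supply sex",
                    analyte))
    }
    sex <- rep_len(as.character(sex), length(value))
    if (!all(sex %in% c("male", "female"))) {
      abort("sex must be 'male' or 'female'")
    }
    w <- numeric(length(value))
    for (sx in c("male", "female")) {
      sel <- sex == sx
      w[sel] <- band_weight(value[sel], comp[[sx]]$bands)
    }
  } else {
    w <- band_weight(value, comp$bands)
  }
  w[is.na(value)] <- 0
  w
}

#' Aggregate LDT-EWS over linked observations
#'
#' Computes the aggregate laboratory early warning score for every row of a
#' linked observation table (see [link_labs()]): the sum of the seven
#' analyte weights, where absent analytes (never measured within the
#' attachment window, or older than the carry-forward horizon) score zero.
#'
#' @param data Data frame with columns `<analyte>_value` for each of
#'   [ldtews_analytes()] (NA = absent), plus either a `sex` column or an
#'   `admission_id` column resolvable through `admissions`.
#' @param admissions Optional admissions table supplying `sex` by
#'   `admission_id` when `data` lacks a `sex` column.
#' @param table An `ews_scoring_table`.
#' @param keep_components Also keep per-analyte weight columns?
#' @return The input as a tibble with an integer `ldtews` column appended
#'   (0 to the declared maximum, 15 by default).
#' @export
score_ldtews <- function(data, admissions = NULL,
                         table = default_scoring_table(),
                         keep_components = FALSE) {
  out <- as_tibble(data)
  if (!"sex" %in% names(out)) {
    if (is.null(admissions)) {
      abort("score_ldtews(): supply a 'sex' column or an admissions table")
    }
    out <- left_join(out,
                     select(admissions, "admission_id", "sex"),
                     by = "admission_id")
  }
  total <- numeric(nrow(out))
  for (an in ldtews_analytes()) {
    col <- paste0(an, "_value")
    if (!col %in% names(out)) {
      abort(sprintf("score_ldtews(): missing column '%s'", col))
    }
    w <- ldtews_component_weight(an, out[[col]], sex = out$sex, table = table)
    if (keep_components) out[[paste0("ldtews_", an)]] <- w
    total <- total + w
  }
  out$ldtews <- as.integer(total)
  out
}
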