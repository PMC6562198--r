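#' Read a scoring table from a YAML definition
#'
#' A scoring table externalises the band cut-offs and integer weights of both
#' component early warning scores: for every NEWS vital-sign input an ordered
#' list of half-open value bands `[lower, upper)` with weights 0--3 (plus the
#' 0/2 supplemental-oxygen weight and the categorical AVPU weights), and for
#' every LDT-EWS analyte the analogous bands, separately for males and
#' females where the cut-offs are sex-specific. The YAML schema is documented
#' in the file shipped at `system.file("extdata", "scoring-table.yaml",
#' package = "ldtnews")`.
#'
#' @param path Path to a YAML file following the documented schema.
#' @return An object of class `ews_scoring_table`: a nested list with
#'   elements `news`, `ldtews` (each holding `max` and `components`),
#'   `gcs_to_avpu` and `plausibility`. Numeric component bands are tibbles
#'   with columns `lower`, `upper`, `weight`.
#' @seealso [default_scoring_table()], [validate_scoring_table()]
#' @export
read_scoring_table <- function(path) {
  raw <- yaml::read_yaml(path)
  for (score in c("news", "ldtews")) {
    if (is.null(raw[[score]])) {
      abort(sprintf("scoring table is missing the '%s' section", score))
    }
    raw[[score]]$components <-
      lapply(raw[[score]]$components, parse_component)
  }
  structure(raw, class = "ews_scoring_table")
}

#' Default scoring table shipped with the package
#'
#' Loads the band/weight transcription installed with the package. The NEWS
#' half is the Royal College of Physicians NEWS (2012) weighting; the
#' LDT-EWS half is a reconstruction using standard adult reference-range
#' cut-offs (sex-specific for haemoglobin and creatinine) whose per-analyte
#' maxima sum to the score's declared maximum of 15. See the YAML file
#' itself and the package vignette for the rationale; supply your own file
#' via [read_scoring_table()] to use different cut-offs.
#'
#' @return An `ews_scoring_table` (see [read_scoring_table()]).
#' @export
#' @examples
#' tab <- default_scoring_table()
#' scoring_table_maxima(tab)
default_scoring_table <- function() {
  read_scoring_table(system.file("extdata", "scoring-table.yaml",
                                 package = "ldtnews", mustWork = TRUE))
}

# normalise one component definition: numeric bands become a lower/upper/
# weight tibble (lower bounds derived from the previous upper; first is -Inf)
parse_component <- function(comp) {
  kind <- comp$kind %||% if (isTRUE(comp$sex_specific)) "numeric" else
    if (!is.null(comp$bands)) "numeric" else NULL
  if (is.null(kind)) abort("component definition has neither bands nor kind")
  comp$kind <- kind
  if (kind == "numeric") {
    if (isTRUE(comp$sex_specific)) {
      for (sx in c("male", "female")) {
        comp[[sx]]$bands <- bands_tibble(comp[[sx]]$bands)
      }
    } else {
      comp$bands <- bands_tibble(comp$bands)
    }
  } else if (kind == "categorical") {
    comp$weights <- unlist(comp$weights)
  }
  comp
}

bands_tibble <- function(bands) {
  upper <- vapply(bands, function(b) as.numeric(b$upper), numeric(1))
  weight <- vapply(bands, function(b) as.numeric(b$weight), numeric(1))
  tibble(lower = c(-Inf, head(upper, -1)), upper = upper, weight = weight)
}

# vectorised half-open band lookup: value v falls in band i iff
# lower[i] <= v < upper[i]
band_weight <- function(values, bands) {
  idx <- findInterval(values, head(bands$upper, -1)) + 1L
  out <- bands$weight[idx]
  out[is.na(values)] <- NA_real_
  out
}

max_component_weight <- function(comp) {
  switch(comp$kind,
    numeric = if (isTRUE(comp$sex_specific)) {
      max(comp$male$bands$weight, comp$female$bands$weight)
    } else {
      max(comp$bands$weight)
    },
    binary = max(comp$weight_true, comp$weight_false),
    categorical = max(comp$weights),
    abort(sprintf("unknown component kind '%s'", comp$kind))
  )
}

#' Maximum attainable aggregate scores under a scoring table
#'
#' Enumerates the worst (highest-weight) band of every component and sums
#' the weights, giving the maximum attainable aggregate NEWS and LDT-EWS.
#' For a well-formed table these equal the declared maxima (20 and 15).
#'
#' @param table An `ews_scoring_table`.
#' @return Named numeric vector with elements `news` and `ldtews`.
#' @export
scoring_table_maxima <- function(table) {
  stopifnot(inherits(table, "ews_scoring_table"))
  c(news = sum(vapply(table$news$components, max_component_weight,
                      numeric(1))),
    ldtews = sum(vapply(table$ldtews$components, max_component_weight,
                        numeric(1))))
}

news_components <- function() {
  c("respiratory_rate", "spo2", "supplemental_oxygen", "temperature",
    "systolic_bp", "heart_rate", "consciousness")
}

#' Validate a scoring table
#'
#' Checks that every expected component is present, that each numeric
#' component's bands tile the real line with no gaps or overlaps (adjacent
#' half-open intervals whose uppers strictly increase, first lower `-Inf`,
#' last upper `+Inf`), that weights are non-negative integers, and that the
#' maximum attainable aggregates equal the declared maxima.
#'
#' @param table An `ews_scoring_table`.
#' @return A tibble of violations with columns `score`, `component`,
#'   `issue`; zero rows when the table is well formed.
#' @export
#' @examples
#' validate_scoring_table(default_scoring_table())
validate_scoring_table <- function(table) {
  stopifnot(inherits(table, "ews_scoring_table"))
  bad <- list()
  note <- function(score, component, issue) {
    bad[[length(bad) + 1L]] <<- tibble(score = score, component = component,
                                       issue = issue)
  }
  expected <- list(news = news_components(), ldtews = ldtews_analytes())
  for (score in names(expected)) {
    comps <- table[[score]]$components
    for (name in expected[[score]]) {
      if (is.null(comps[[name]])) note(score, name, "missing variable")
    }
    for (name in setdiff(names(comps), expected[[score]])) {
      note(score, name, "unknown variable")
    }
    for (name in intersect(names(comps), expected[[score]])) {
      comp <- comps[[name]]
      if (comp$kind == "numeric") {
        band_sets <- if (isTRUE(comp$sex_specific)) {
          list(male = comp$male$bands, female = comp$female$bands)
        } else {
          list(all = comp$bands)
        }
        for (sx in names(band_sets)) {
          b <- band_sets[[sx]]
          lab <- if (sx == "all") name else paste0(name, " (", sx, ")")
          if (is.unsorted(b$upper, strictly = TRUE)) {
            note(score, lab, "overlap")  # non-increasing uppers => overlap
          }
          if (!identical(b$lower[1], -Inf) ||
              !identical(b$upper[nrow(b)], Inf)) {
            note(score, lab, "gap")  # domain not fully tiled
          }
          if (any(b$weight < 0) || any(b$weight != round(b$weight))) {
            note(score, lab, "non-integer or negative weight")
          }
        }
      }
    }
    declared <- table[[score]]$max
    attained <- sum(vapply(comps[intersect(names(comps),
                                           expected[[score]])],
                           max_component_weight, numeric(1)))
    if (length(declared) != 1 || attained != declared) {
      note(score, NA_character_,
           sprintf("attainable maximum %s differs from declared %s",
                   attained, declared))
    }
  }
  if (length(bad) == 0) {
    tibble(score = character(), component = character(), issue = character())
  } else {
    bind_rows(bad)
  }
}

#' @export
print.ews_scoring_table <- function(x, ...) {
  m <- scoring_table_maxima(x)
  cat("<ews_scoring_table>\n")
  cat(sprintf("  NEWS: %d components, max %g (declared %g)\n",
              length(x$news$components), m[["news"]], x$news$max))
  cat(sprintf("  LDT-EWS: %d analytes, max %g (declared %g)\n",
              length(x$ldtews$components), m[["ldtews"]], x$ldtews$max))
  invisible(x)
}
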