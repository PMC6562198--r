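check_two_classes <- function(labels) {
  labels <- as.logical(labels)
  if (anyNA(labels)) abort("labels must not contain NA")
  if (all(labels) || !any(labels)) {
    abort("both outcome classes must be present")
  }
  labels
}

#' Concordance statistic (AUROC)
#'
#' The probability that a randomly chosen event-positive observation scores
#' higher than a randomly chosen negative one, with ties counted one half:
#' the Mann--Whitney form of the area under the ROC curve, computed via
#' midranks.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) outcome labels.
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' c_statistic(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
c_statistic <- function(scores, labels) {
  labels <- check_two_classes(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  auroc_rank(scores, labels)
}

#' DeLong confidence interval for the c-statistic
#'
#' Normal-approximation interval using the DeLong variance estimate from
#' per-observation placement values, clipped to `[0, 1]`. When every score
#' is identical the variance degenerates; the interval is then reported as
#' the full unit interval and flagged.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) outcome labels.
#' @param level Confidence level (default 0.95).
#' @return One-row tibble: `estimate`, `conf_low`, `conf_high`, `se`,
#'   `level`, `n_pos`, `n_neg`, `degenerate`.
#' @export
c_statistic_ci <- function(scores, labels, level = 0.95) {
  labels <- check_two_classes(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores),
            level > 0, level < 1)
  x <- scores[labels]
  y <- scores[!labels]
  m <- length(x)
  n <- length(y)
  auc <- auroc_rank(scores, labels)
  # placements via ranks: V10_i = (rank of x_i among all - rank among x) / n
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
  s10 <- stats::var(v10)
  s01 <- stats::var(v01)
  se <- sqrt(s10 / m + s01 / n)
  degenerate <- length(unique(scores)) == 1
  if (degenerate) {
    lo <- 0
    hi <- 1
  } else {
    z <- qnorm(1 - (1 - level) / 2)
    lo <- max(0, auc - z * se)
    hi <- min(1, auc + z * se)
  }
  tibble(estimate = auc, conf_low = lo, conf_high = hi, se = se,
         level = level, n_pos = m, n_neg = n, degenerate = degenerate)
}

#' ROC curve points
#'
#' One `(FPR, TPR)` point per distinct threshold, using the "flag when
#' score >= threshold" convention, forming the monotone staircase from
#' `(0, 0)` (threshold `Inf`) to `(1, 1)` (threshold at the minimum score).
#' The trapezoidal area under the returned points equals [c_statistic()]
#' exactly.
#'
#' @inheritParams c_statistic
#' @return Tibble with columns `threshold`, `fpr`, `tpr`, ordered by
#'   increasing `fpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_two_classes(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last_of_run <- c(s[-1] != s[-length(s)], TRUE)
  tibble(
    threshold = c(Inf, s[last_of_run]),
    fpr = c(0, cumsum(!y)[last_of_run] / n0),
    tpr = c(0, cumsum(y)[last_of_run] / n1)
  )
}

#' Binned calibration table
#'
#' Bins scores into equal-width bins over `[0, 1]` and reports, per
#' non-empty bin, the mean score and the observed event rate -- the tabular
#' form of a visual calibration assessment for a risk score on the unit
#' interval.
#'
#' @inheritParams c_statistic
#' @param bin_width Bin width (default 0.05); scores of exactly 1 fall in
#'   the last bin.
#' @return Tibble with columns `bin_low`, `bin_high`, `mean_score`,
#'   `event_rate`, `n`; empty bins are omitted, so `sum(n)` equals the
#'   number of observations.
#' @export
calibration_table <- function(scores, labels, bin_width = 0.05) {
  stopifnot(!anyNA(scores), all(scores >= 0), all(scores <= 1),
            bin_width > 0, bin_width <= 1)
  labels <- as.logical(labels)
  n_bins <- ceiling(1 / bin_width)
  bin <- pmin(floor(scores / bin_width), n_bins - 1) + 1L
  tibble(bin = bin, score = scores, label = labels) %>%
    group_by(.data$bin) %>%
    summarise(mean_score = mean(.data$score),
              event_rate = mean(.data$label),
              n = n(), .groups = "drop") %>%
    mutate(bin_low = (.data$bin - 1L) * bin_width,
           bin_high = pmin(.data$bin * bin_width, 1)) %>%
    select("bin_low", "bin_high", "mean_score", "event_rate", "n")
}

#' Sensitivity/specificity report at a threshold
#'
#' Flags observations with `score >= threshold` and reports sensitivity,
#' specificity, positive and negative predictive value, and the number
#' flagged. PPV is `NA` when nothing is flagged; NPV is `NA` when
#' everything is.
#'
#' @inheritParams c_statistic
#' @param threshold Flagging cut-off.
#' @return One-row tibble: `threshold`, `n_flagged`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`.
#' @export
threshold_report <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores),
            !anyNA(labels), length(threshold) == 1)
  flag <- scores >= threshold
  tp <- sum(flag & labels)
  fp <- sum(flag & !labels)
  fn <- sum(!flag & labels)
  tn <- sum(!flag & !labels)
  tibble(
    threshold = threshold,
    n_flagged = tp + fp,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

#' Specificity-matched threshold comparison
#'
#' Given a reference score with an established trigger level (e.g. NEWS at
#' 5 or 7), finds the smallest threshold on a second score whose
#' specificity on the same labelled observations is at least the
#' reference's, and reports the operating characteristics of both. This is
#' how a new score's PPV is compared with an incumbent's at comparable
#' specificity.
#'
#' @param reference_scores Scores of the incumbent (e.g. aggregate NEWS).
#' @param reference_threshold The incumbent's trigger level.
#' @param target_scores Scores of the new index on the same observations.
#' @param labels Shared outcome labels.
#' @return Tibble with two rows (`score` = `"reference"`, `"target"`) and
#'   the [threshold_report()] columns plus `matched`: `FALSE` on the target
#'   row when the reference specificity is unattainable, in which case the
#'   max-specificity threshold is reported.
#' @export
matched_specificity_threshold <- function(reference_scores,
                                          reference_threshold,
                                          target_scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(reference_scores) == length(labels),
            length(target_scores) == length(labels))
  ref <- threshold_report(reference_scores, labels, reference_threshold)
  candidates <- sort(unique(target_scores))
  spec <- vapply(candidates, function(th) {
    neg <- !labels
    sum(target_scores < th & neg) / sum(neg)
  }, numeric(1))
  ok <- spec >= ref$specificity
  if (any(ok)) {
    th <- candidates[which(ok)[1]]  # specificity is monotone in threshold
    matched <- TRUE
  } else {
    th <- candidates[which.max(spec)]
    matched <- FALSE
  }
  tgt <- threshold_report(target_scores, labels, th)
  out <- bind_rows(
    mutate(ref, score = "reference", matched = TRUE),
    mutate(tgt, score = "target", matched = matched)
  )
  select(out, "score", "threshold", "n_flagged", "sensitivity",
         "specificity", "ppv", "npv", "matched")
}

#' Discrimination summary for several scores and outcomes
#'
#' Convenience wrapper: c-statistic with DeLong interval for each supplied
#' score column against each outcome column.
#'
#' @param data Observation-level tibble.
#' @param score_cols Named character vector of score columns (names are
#'   display labels; defaults cover NEWS, LDT-EWS, the decayed index and
#'   the fixed-weight comparator).
#' @param outcome_cols Character vector of logical outcome columns.
#' @param level Confidence level.
#' @return Tibble with one row per score x outcome combination; outcomes
#'   with a single class (e.g. no ICU events in a small cohort) are
#'   skipped.
#' @export
evaluate_scores <- function(data,
                            score_cols = c(news = "news",
                                           ldtews = "ldtews",
                                           risk_index = "risk_index",
                                           fixed_index = "fixed_index"),
                            outcome_cols = c("outcome_primary_24h",
                                             "outcome_death_24h",
                                             "outcome_icu_24h"),
                            level = 0.95) {
  score_cols <- score_cols[score_cols %in% names(data)]
  outcome_cols <- intersect(outcome_cols, names(data))
  # an outcome with no events (or all events) has no defined AUROC; skip it
  outcome_cols <- outcome_cols[vapply(outcome_cols, function(oc) {
    length(unique(as.logical(data[[oc]]))) == 2
  }, logical(1))]
  rows <- list()
  for (oc in outcome_cols) {
    for (i in seq_along(score_cols)) {
      ci <- c_statistic_ci(data[[score_cols[[i]]]], data[[oc]],
                           level = level)
      rows[[length(rows) + 1L]] <-
        mutate(ci, score = names(score_cols)[i], outcome = oc)
    }
  }
  select(bind_rows(rows), "score", "outcome", "estimate", "conf_low",
         "conf_high", "se", "n_pos", "n_neg")
}
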