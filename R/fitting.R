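#' Random admission-level folds
#'
#' Partitions admissions into near-equal random folds. All observation sets
#' of one admission share a fold, preventing within-admission leakage into
#' the cross-validated grid search.
#'
#' @param admission_ids Vector of admission identifiers (duplicates
#'   allowed; folds are assigned to the unique ids, sorted first so the
#'   assignment does not depend on input ordering).
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed; the same seed always yields the same
#'   assignment.
#' @return Tibble with columns `admission_id`, `fold`; fold sizes differ by
#'   at most one.
#' @export
#' @examples
#' make_folds(sprintf("a%03d", 1:23), n_folds = 10, seed = 1)
make_folds <- function(admission_ids, n_folds = 10, seed = 1) {
  ids <- sort(unique(admission_ids))
  if (length(ids) < n_folds) {
    abort(sprintf("need at least %d admissions for %d folds, got %d",
                  n_folds, n_folds, length(ids)))
  }
  fold <- withr::with_seed(seed,
                           sample(rep_len(seq_len(n_folds), length(ids))))
  tibble(admission_id = ids, fold = fold)
}

# Mann-Whitney AUROC via midranks; assumes both classes present.
# counts kept in double precision: n1 * (n1 + 1) overflows integers
# around n1 ~ 46k
auroc_rank <- function(scores, labels) {
  n1 <- as.numeric(sum(labels))
  n0 <- length(labels) - n1
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit the decay coefficient by cross-validated grid search
#'
#' Estimates the decay coefficient of the combined risk index. The data are
#' split randomly into admission-level folds; for every candidate value on
#' the grid, the risk index is computed on each fold's observations and
#' that fold's AUROC against the primary outcome recorded; the fitted
#' coefficient is the grid value with the maximal mean AUROC across folds
#' (ties broken towards the smallest value). The full coefficient-vs-mean-
#' AUROC curve is returned for inspection.
#'
#' @param data Observation-level tibble with columns `admission_id`, `news`,
#'   `ldtews`, `time_since_labs` and `outcome_primary_24h`.
#' @param grid Strictly increasing candidate values in (0, 1); default
#'   0.01, 0.02, ..., 0.99.
#' @param n_folds Number of admission-level folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param horizon_hours Decay horizon passed to [decay_weight()].
#' @param news_max,ldtews_max Normalising maxima of the two scores.
#' @return An object of class `ldtnews_fit` with elements `beta` (the
#'   fitted coefficient), `curve` (tibble `beta`, `mean_auroc`),
#'   `fold_auroc` (tibble `beta`, `fold`, `auroc`), `n_obs`,
#'   `n_admissions`, `n_folds`, `seed`. Supports [tidy()], [glance()],
#'   [autoplot()] and `print()`.
#' @export
fit_beta <- function(data, grid = seq(0.01, 0.99, by = 0.01), n_folds = 10,
                     seed = 1, horizon_hours = 120, news_max = 20,
                     ldtews_max = 15) {
  needed <- c("admission_id", "news", "ldtews", "time_since_labs",
              "outcome_primary_24h")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("fit_beta(): missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (length(grid) < 1 || any(grid <= 0) || any(grid >= 1) ||
      is.unsorted(grid, strictly = TRUE)) {
    abort("grid must be strictly increasing values in (0, 1)")
  }
  data <- as_tibble(data)
  folds <- make_folds(data$admission_id, n_folds = n_folds, seed = seed)
  fold_of <- folds$fold[match(data$admission_id, folds$admission_id)]

  # index at coefficient b decomposes as base + b * lever, so the per-fold
  # work is one rank per (fold, b) pair
  base <- data$news / news_max
  lever <- decay_weight(data$time_since_labs, beta = 0.5,
                        horizon_hours = horizon_hours) / 0.5 *
    (data$ldtews / ldtews_max - base)
  labels <- as.logical(data$outcome_primary_24h)

  fold_auroc <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    sel <- fold_of == f
    y <- labels[sel]
    if (length(unique(y)) < 2) {
      abort(sprintf(
        paste0("fold %d contains a single outcome class; AUROC is ",
               "undefined. Use more data or fewer folds."), f))
    }
    b0 <- base[sel]
    lv <- lever[sel]
    a <- vapply(grid, function(b) auroc_rank(b0 + b * lv, y), numeric(1))
    fold_auroc[[f]] <- tibble(beta = grid, fold = f, auroc = a)
  }
  fold_auroc <- bind_rows(fold_auroc)
  curve <- fold_auroc %>%
    group_by(.data$beta) %>%
    summarise(mean_auroc = mean(.data$auroc), .groups = "drop") %>%
    arrange(.data$beta)
  beta_hat <- curve$beta[which.max(curve$mean_auroc)]
  structure(list(beta = beta_hat, curve = curve, fold_auroc = fold_auroc,
                 n_obs = nrow(data),
                 n_admissions = length(unique(data$admission_id)),
                 n_folds = n_folds, seed = seed, grid = grid),
            class = "ldtnews_fit")
}

#' @export
print.ldtnews_fit <- function(x, ...) {
  cat("<ldtnews_fit>\n")
  cat(sprintf("  beta = %.2f (grid of %d values, %d folds, seed %d)\n",
              x$beta, length(x$grid), x$n_folds, x$seed))
  cat(sprintf("  mean AUROC at beta: %.4f over %d observations / %d admissions\n",
              max(x$curve$mean_auroc), x$n_obs, x$n_admissions))
  invisible(x)
}

#' @rdname fit_beta
#' @param x,object An `ldtnews_fit`.
#' @param ... Unused.
#' @method tidy ldtnews_fit
#' @export
tidy.ldtnews_fit <- function(x, ...) {
  x$curve
}

#' @rdname fit_beta
#' @method glance ldtnews_fit
#' @export
glance.ldtnews_fit <- function(x, ...) {
  tibble(beta = x$beta, mean_auroc = max(x$curve$mean_auroc),
         n_obs = x$n_obs, n_admissions = x$n_admissions,
         n_folds = x$n_folds, seed = x$seed)
}

#' @rdname fit_beta
#' @method autoplot ldtnews_fit
#' @export
autoplot.ldtnews_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$beta, y = .data$mean_auroc)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$beta, linetype = "dashed") +
    ggplot2::labs(x = "decay coefficient",
                  y = "mean AUROC across folds",
                  title = sprintf("Grid search: fitted coefficient %.2f",
                                  object$beta)) +
    ggplot2::theme_minimal()
}
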