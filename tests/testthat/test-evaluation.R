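test_that("c-statistic handles separation, ties, and errors", {
  expect_equal(c_statistic(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(c_statistic(rep(2, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(c_statistic(1:5, rep(1, 5)), "both outcome classes")
})

test_that("c-statistic equals the exhaustive pairwise oracle", {
  withr::with_seed(55, {
    for (rep in 1:25) {
      n <- sample(20:400, 1)
      # heavy ties: integer scores over a narrow range
      scores <- sample(0:12, n, replace = TRUE)
      labels <- runif(n) < 0.3
      if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
      expect_equal(c_statistic(scores, labels),
                   oracle_auroc(scores, labels), tolerance = 1e-12)
    }
  })
})

test_that("c-statistic is invariant under strictly increasing transforms", {
  withr::with_seed(4, {
    scores <- rnorm(300)
    labels <- runif(300) < plogis(scores)
    a <- c_statistic(scores, labels)
    expect_equal(c_statistic(exp(scores), labels), a, tolerance = 1e-12)
    expect_equal(c_statistic(rank(scores), labels), a, tolerance = 1e-12)
    expect_equal(c_statistic(-scores, labels), 1 - a, tolerance = 1e-12)
  })
})

test_that("DeLong interval matches pROC and clips at the boundary", {
  skip_if_not_installed("pROC")
  withr::with_seed(20, {
    for (rep in 1:5) {
      scores <- c(rnorm(80, 1), rnorm(120))
      labels <- rep(c(TRUE, FALSE), c(80, 120))
      got <- c_statistic_ci(scores, labels)
      ref <- suppressMessages(pROC::ci.auc(pROC::roc(labels, scores,
                                                     quiet = TRUE)))
      expect_equal(got$estimate, as.numeric(ref[2]), tolerance = 1e-10)
      expect_equal(got$conf_low, as.numeric(ref[1]), tolerance = 1e-10)
      expect_equal(got$conf_high, as.numeric(ref[3]), tolerance = 1e-10)
    }
  })
  sep <- c_statistic_ci(c(1, 1, 2, 2), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(sep$conf_high, 1.0)
  deg <- c_statistic_ci(rep(1, 20), rep(c(TRUE, FALSE), 10))
  expect_true(deg$degenerate)
  expect_equal(c(deg$conf_low, deg$conf_high), c(0, 1))
})

test_that("DeLong interval covers the closed-form binormal AUROC", {
  # scores one SD apart with unit variances: AUROC = pnorm(1/sqrt(2))
  target <- pnorm(1 / sqrt(2))
  withr::with_seed(99, {
    inside <- 0
    contains_est <- TRUE
    for (rep in 1:100) {
      scores <- c(rnorm(500, 1), rnorm(500))
      labels <- rep(c(TRUE, FALSE), each = 500)
      ci <- c_statistic_ci(scores, labels)
      inside <- inside + (ci$conf_low <= target && target <= ci$conf_high)
      contains_est <- contains_est &&
        (ci$conf_low <= ci$estimate && ci$estimate <= ci$conf_high)
    }
    expect_gte(inside, 90)
    expect_true(contains_est)
  })
})

test_that("ROC curve is a consistent staircase", {
  withr::with_seed(17, {
    scores <- sample(0:20, 400, replace = TRUE)
    labels <- runif(400) < plogis(-3 + 0.3 * scores)
    labels[1:2] <- c(TRUE, FALSE)
    rc <- roc_curve(scores, labels)
    expect_equal(rc$fpr[1], 0)
    expect_equal(rc$tpr[1], 0)
    expect_equal(rc$fpr[nrow(rc)], 1)
    expect_equal(rc$tpr[nrow(rc)], 1)
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
    # trapezoidal area equals the c-statistic exactly
    area <- sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + rc$tpr[-1]) / 2)
    expect_equal(area, c_statistic(scores, labels), tolerance = 1e-12)
    # perfect separation passes through (0, 1)
    rp <- roc_curve(c(1, 2, 5, 6), c(0, 0, 1, 1))
    expect_true(any(rp$fpr == 0 & rp$tpr == 1))
  })
})

test_that("calibration bins partition the data and track planted rates", {
  withr::with_seed(31, {
    scores <- runif(20000)
    labels <- runif(20000) < scores
    cal <- calibration_table(scores, labels)
    expect_equal(sum(cal$n), 20000L)
    expect_true(all(cal$event_rate >= 0 & cal$event_rate <= 1))
    # every bin within simultaneous (Bonferroni-adjusted) binomial bounds,
    # and the bulk within plain per-bin 95% bounds
    a <- 0.025 / nrow(cal)
    lo <- qbinom(a, cal$n, cal$mean_score) / cal$n
    hi <- qbinom(1 - a, cal$n, cal$mean_score) / cal$n
    expect_true(all(cal$event_rate >= lo & cal$event_rate <= hi))
    lo95 <- qbinom(0.025, cal$n, cal$mean_score) / cal$n
    hi95 <- qbinom(0.975, cal$n, cal$mean_score) / cal$n
    expect_gte(mean(cal$event_rate >= lo95 & cal$event_rate <= hi95), 0.9)
  })
  cal0 <- calibration_table(runif(100), rep(FALSE, 100))
  expect_true(all(cal0$event_rate == 0))
  # scores of exactly 1 land in the final bin
  cal1 <- calibration_table(c(0, 0.5, 1), c(FALSE, TRUE, TRUE))
  expect_equal(max(cal1$bin_high), 1)
  expect_equal(sum(cal1$n), 3L)
})

test_that("threshold reports flag score >= threshold", {
  scores <- c(1, 3, 5, 7)
  labels <- c(FALSE, FALSE, TRUE, TRUE)
  rep5 <- threshold_report(scores, labels, 5)
  expect_equal(rep5$n_flagged, 2L)
  expect_equal(rep5$sensitivity, 1)
  expect_equal(rep5$specificity, 1)
  expect_equal(rep5$ppv, 1)
  expect_equal(rep5$npv, 1)
  rep_high <- threshold_report(scores, labels, 100)
  expect_equal(rep_high$n_flagged, 0L)
  expect_true(is.na(rep_high$ppv))
})

test_that("matched-specificity thresholds behave under identity and rescaling", {
  withr::with_seed(71, {
    scores <- sample(0:20, 600, replace = TRUE)
    labels <- runif(600) < plogis(-4 + 0.35 * scores)
    labels[1:2] <- c(TRUE, FALSE)

    ident <- matched_specificity_threshold(scores, 5, scores, labels)
    expect_equal(ident$threshold[ident$score == "target"], 5)
    expect_true(all(ident$matched))

    scaled <- matched_specificity_threshold(scores, 5, scores / 20, labels)
    expect_equal(scaled$threshold[scaled$score == "target"], 5 / 20)
    tgt <- scaled[scaled$score == "target", ]
    ref <- scaled[scaled$score == "reference", ]
    expect_equal(tgt$specificity, ref$specificity)
    expect_equal(tgt$sensitivity, ref$sensitivity)

    # unattainable specificity: all target scores equal
    flat <- matched_specificity_threshold(scores, 5, rep(1, 600), labels)
    expect_false(flat$matched[flat$score == "target"])
  })
})

test_that("evaluate_scores summarises every score/outcome pair", {
  withr::with_seed(3, {
    d <- tibble::tibble(
      news = sample(0:20, 300, TRUE),
      risk_index = runif(300),
      outcome_primary_24h = runif(300) < 0.2,
      outcome_death_24h = runif(300) < 0.15
    )
    d$outcome_primary_24h[1:2] <- c(TRUE, FALSE)
    d$outcome_death_24h[1:2] <- c(TRUE, FALSE)
    ev <- evaluate_scores(d)
    expect_equal(nrow(ev), 4L)  # 2 scores x 2 outcomes present
    expect_true(all(ev$estimate >= 0 & ev$estimate <= 1))
  })
})
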