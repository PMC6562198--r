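#' Plot one or more ROC curves
#'
#' @param curves A tibble from [roc_curve()], or a named list of them (one
#'   curve per score).
#' @return A ggplot object.
#' @export
plot_roc <- function(curves) {
  if (is.data.frame(curves)) curves <- list(score = curves)
  df <- bind_rows(curves, .id = "score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$score)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Plot a binned calibration table
#'
#' Observed event rate against mean predicted risk per bin, with the
#' identity line as the perfect-calibration reference; point size reflects
#' bin occupancy.
#'
#' @param calibration A tibble from [calibration_table()].
#' @return A ggplot object.
#' @export
plot_calibration <- function(calibration) {
  ggplot2::ggplot(calibration,
                  ggplot2::aes(x = .data$mean_score, y = .data$event_rate,
                               size = .data$n)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "mean risk index in bin",
                  y = "observed event rate") +
    ggplot2::theme_minimal()
}
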