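#' Linear time-decay weight on the laboratory component
#'
#' The weight placed on the (normalised) LDT-EWS term of the combined risk
#' index decays linearly with the age of the most recent laboratory result:
#' \deqn{\omega = \beta \left(1 - \frac{\min(t, H)}{H}\right)}
#' where `t` is `time_since_labs` in hours and `H` is the horizon (120 h by
#' default). Fresh results (`t = 0`) get the full coefficient `beta`;
#' results at or beyond the horizon get weight 0, at which point the index
#' reduces to NEWS alone.
#'
#' @param time_since_labs Hours since the most recent linked laboratory
#'   result (non-negative; vectorised).
#' @param beta Decay coefficient in `[0, 1)`. The development-phase value
#'   estimated by cross-validated grid search is 0.26 (see [fit_beta()]).
#' @param horizon_hours Decay horizon in hours (default 120).
#' @return Numeric vector of weights in `[0, beta]`.
#' @export
#' @examples
#' decay_weight(c(0, 60, 120, 200), beta = 0.26)
decay_weight <- function(time_since_labs, beta, horizon_hours = 120) {
  if (any(!is.na(time_since_labs) & time_since_labs < 0)) {
    abort("time_since_labs must be non-negative")
  }
  if (length(beta) != 1 || is.na(beta) || beta < 0 || beta >= 1) {
    abort("beta must be a single value in [0, 1)")
  }
  stopifnot(horizon_hours > 0)
  beta * (1 - pmin(time_since_labs, horizon_hours) / horizon_hours)
}

check_aggregates <- function(news, ldtews, news_max, ldtews_max) {
  if (any(!is.na(news) & (news < 0 | news > news_max))) {
    abort(sprintf("news aggregate outside [0, %g]", news_max))
  }
  if (any(!is.na(ldtews) & (ldtews < 0 | ldtews > ldtews_max))) {
    abort(sprintf("ldtews aggregate outside [0, %g]", ldtews_max))
  }
}

#' Combined LDTEWS:NEWS risk index
#'
#' Weighted sum of the two aggregate scores, each normalised by its maximum
#' attainable value so both lie on a common 0--1 scale:
#' \deqn{\mathrm{index} = \omega \frac{\mathrm{LDTEWS}}{15} +
#'   (1 - \omega) \frac{\mathrm{NEWS}}{20}}
#'
#' @param news Aggregate NEWS (0--`news_max`).
#' @param ldtews Aggregate LDT-EWS (0--`ldtews_max`).
#' @param omega Weight on the laboratory term, in `[0, 1]` (usually from
#'   [decay_weight()]).
#' @param news_max,ldtews_max Normalising maxima (20 and 15).
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' risk_index(news = 5, ldtews = 3, omega = 0.26)
risk_index <- function(news, ldtews, omega, news_max = 20, ldtews_max = 15) {
  if (any(!is.na(omega) & (omega < 0 | omega > 1))) {
    abort("omega must lie in [0, 1]")
  }
  check_aggregates(news, ldtews, news_max, ldtews_max)
  omega * (ldtews / ldtews_max) + (1 - omega) * (news / news_max)
}

#' Fixed-weight comparator index
#'
#' The variant of the combined score in which the laboratory weight is held
#' at `omega = beta` regardless of how old the laboratory results are
#' (i.e. without the linear decay). Used as a comparator when assessing
#' whether the decay itself adds discrimination.
#'
#' @inheritParams risk_index
#' @param beta Fixed weight in `[0, 1)`.
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' fixed_weight_index(news = 8, ldtews = 0, beta = 0.26)
fixed_weight_index <- function(news, ldtews, beta, news_max = 20,
                               ldtews_max = 15) {
  if (length(beta) != 1 || is.na(beta) || beta < 0 || beta >= 1) {
    abort("beta must be a single value in [0, 1)")
  }
  risk_index(news, ldtews, omega = beta, news_max = news_max,
             ldtews_max = ldtews_max)
}

#' Add the decay weight and risk index to a scored observation table
#'
#' Convenience verb for pipelines: given rows carrying `news`, `ldtews` and
#' `time_since_labs` (see [score_news()], [score_ldtews()], [link_labs()]),
#' appends `omega`, `risk_index` and the fixed-weight comparator
#' `fixed_index`.
#'
#' @param data Data frame with `news`, `ldtews`, `time_since_labs` columns.
#' @param beta Decay coefficient in `[0, 1)`.
#' @param horizon_hours Decay horizon in hours.
#' @param news_max,ldtews_max Normalising maxima.
#' @return The input as a tibble with `omega`, `risk_index` and
#'   `fixed_index` columns appended.
#' @export
add_risk_index <- function(data, beta, horizon_hours = 120, news_max = 20,
                           ldtews_max = 15) {
  needed <- c("news", "ldtews", "time_since_labs")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("add_risk_index(): missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(data)
  out$omega <- decay_weight(out$time_since_labs, beta, horizon_hours)
  out$risk_index <- risk_index(out$news, out$ldtews, out$omega,
                               news_max, ldtews_max)
  out$fixed_index <- fixed_weight_index(out$news, out$ldtews, beta,
                                        news_max, ldtews_max)
  out
}
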