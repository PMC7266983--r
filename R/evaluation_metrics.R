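#' Variability magnitude on the exposure scale
#'
#' Expresses the spread of a set of positive exposures (AUCs) or doses as a
#' percent coefficient on the log scale: 100 times the population standard
#' deviation (divisor N) of `ln(x)`. Applied to per-occasion AUCs of one
#' individual it quantifies inter-occasion variability; applied to
#' per-subject AUCs it quantifies inter-individual variability. The measure
#' is scale invariant: multiplying all values by a constant leaves it
#' unchanged.
#'
#' @param x positive values (length >= 2).
#' @return variability magnitude, percent.
#' @export
#' @examples
#' variability_magnitude(c(100 * exp(0.5), 100, 100 * exp(-0.5))) # 40.82
variability_magnitude <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("all values must be positive and finite", call. = FALSE)
  }
  if (length(x) < 2) stop("need at least two values", call. = FALSE)
  lx <- log(x)
  100 * sqrt(mean((lx - mean(lx))^2))
}

#' Order-statistic prediction interval
#'
#' Two-sided prediction interval from the `(N + 1) * alpha`-th and
#' `(N + 1) * (1 - alpha)`-th elements of the ordered values, with linear
#' interpolation at fractional ranks (the type-6 quantile definition),
#' where `alpha = (1 - level) / 2`.
#'
#' @param x values.
#' @param level interval level in (0, 1), default 0.95.
#' @return named vector `c(lower, upper)`.
#' @export
#' @examples
#' prediction_interval(1:39, 0.95) # exactly the sample minimum and maximum
prediction_interval <- function(x, level = 0.95) {
  stopifnot(level > 0, level < 1)
  alpha <- (1 - level) / 2
  n <- length(x)
  if (n < 1 / alpha - 1) {
    stop("need at least ", ceiling(1 / alpha - 1),
         " values for a ", 100 * level, "% interval", call. = FALSE)
  }
  setNames(quantile(x, probs = c(alpha, 1 - alpha), type = 6, names = FALSE),
           c("lower", "upper"))
}

#' Individual dose prediction error
#'
#' `100 * (dose_mipd - dose_true) / dose_true`: the signed percent deviation
#' of the forecasted dose from the subject's true optimal dose.
#'
#' @param dose_mipd forecasted dose, mg (vectorised).
#' @param dose_true true optimal dose, mg (> 0).
#' @return prediction error, percent.
#' @export
#' @examples
#' individual_prediction_error(1500, 1800) # -16.67
individual_prediction_error <- function(dose_mipd, dose_true) {
  if (any(dose_true <= 0)) stop("true doses must be positive", call. = FALSE)
  100 * (dose_mipd - dose_true) / dose_true
}

#' Bias and imprecision of dose predictions
#'
#' Mean absolute percentage error (bias) and relative root mean square error
#' (imprecision) of forecasted versus true doses:
#' `MAPE = 100/N * sum(|pred - true| / true)` and
#' `rRMSE = 100 * sqrt(1/N * sum((pred - true)^2 / true^2))`. Both are zero
#' exactly when every prediction is exact.
#'
#' @param pred forecasted doses, mg.
#' @param true true doses, mg (> 0, same length).
#' @return percent.
#' @export
#' @examples
#' mape(c(1500, 1800), c(1800, 1800)) # 8.33
#' rrmse(c(1500, 1800), c(1800, 1800)) # 11.79
mape <- function(pred, true) {
  check_paired(pred, true)
  100 * mean(abs(pred - true) / true)
}

#' @rdname mape
#' @export
rrmse <- function(pred, true) {
  check_paired(pred, true)
  100 * sqrt(mean((pred - true)^2 / true^2))
}

check_paired <- function(pred, true) {
  if (length(pred) != length(true)) {
    stop("prediction and truth vectors must have equal length", call. = FALSE)
  }
  if (any(true <= 0)) stop("true doses must be positive", call. = FALSE)
  invisible(TRUE)
}

#' Paired bootstrap CI for a metric difference between two MIPD arms
#'
#' Nonparametric paired bootstrap over subjects of the difference
#' `metric(arm_b) - metric(arm_a)` for a dose-prediction metric such as
#' [mape()] or [rrmse()]. Both arms must be paired by subject (same true
#' doses). The difference is judged statistically significant when the
#' percentile confidence interval excludes zero.
#'
#' @param metric `"mape"`, `"rrmse"`, or a function `(pred, true) ->`
#'   scalar.
#' @param pred_a,pred_b forecasted doses of the two arms, paired by
#'   position.
#' @param true true doses shared by both arms.
#' @param level confidence level.
#' @param B number of bootstrap resamples.
#' @param seed optional integer seed.
#' @return one-row tibble with `estimate` (the observed difference),
#'   `lower`, `upper`, `significant`.
#' @export
paired_difference_ci <- function(metric, pred_a, pred_b, true,
                                 level = 0.95, B = 2000, seed = NULL) {
  if (is.character(metric)) {
    metric <- switch(metric, mape = mape, rrmse = rrmse,
                     stop("unknown metric '", metric, "'", call. = FALSE))
  }
  n <- length(true)
  if (length(pred_a) != n || length(pred_b) != n) {
    stop("arms must be paired by subject (equal lengths)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  est <- metric(pred_b, true) - metric(pred_a, true)
  diffs <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    metric(pred_b[idx], true[idx]) - metric(pred_a[idx], true[idx])
  }, numeric(1))
  alpha <- (1 - level) / 2
  ci <- quantile(diffs, c(alpha, 1 - alpha), names = FALSE)
  tibble::tibble(estimate = est, lower = ci[1], upper = ci[2],
                 significant = ci[1] > 0 | ci[2] < 0)
}
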