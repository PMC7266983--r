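#' Plot per-occasion exposures of the typical patient
#'
#' A random subset of simulated sampling occasions with the steady-state
#' acceptable AUC range as dashed lines, illustrating how strongly the
#' exposure of one and the same patient varies between occasions.
#'
#' @param x result of [experiment_iov_typical()].
#' @param n_show number of occasions to display.
#' @param target acceptable AUC range shown as dashed lines (default the
#'   steady-state row of [target_table()]).
#' @param seed seed for the occasion subsample.
#' @return a ggplot object.
#' @export
plot_occasion_aucs <- function(x, n_show = 20,
                               target = auc_target_range(56), seed = 1) {
  set.seed(seed)
  idx <- sort(sample(nrow(x$aucs), min(n_show, nrow(x$aucs))))
  df <- tibble::tibble(occasion = seq_along(idx), auc = x$aucs$auc[idx])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$occasion, y = .data$auc)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = target, linetype = "dashed") +
    ggplot2::labs(x = "Sampling occasion",
                  y = expression(AUC["0-24h"] ~ "(h mg/L)"),
                  title = "Steady-state exposure across occasions (IOV only)") +
    ggplot2::theme_bw()
}

#' Compare the magnitudes of between-patient and between-occasion spread
#'
#' Box-style summary (median, 50\% box, 95\% whiskers, all order-statistic
#' quantiles) of the AUC distributions from the IIV-only population
#' experiment and the IOV-only typical-patient experiment.
#'
#' @param iiv result of [experiment_iiv_population()].
#' @param iov result of [experiment_iov_typical()].
#' @return a ggplot object.
#' @export
plot_variability <- function(iiv, iov) {
  mk <- function(x, lab) {
    tibble::tibble(
      source = lab, middle = median(x),
      lower = prediction_interval(x, 0.5)[1],
      upper = prediction_interval(x, 0.5)[2],
      ymin = prediction_interval(x, 0.95)[1],
      ymax = prediction_interval(x, 0.95)[2]
    )
  }
  df <- dplyr::bind_rows(mk(iiv$subjects$auc, "IIV"), mk(iov$aucs$auc, "IOV"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$ymin, lower = .data$lower,
                   middle = .data$middle, upper = .data$upper,
                   ymax = .data$ymax),
      stat = "identity", width = 0.5
    ) +
    ggplot2::labs(x = NULL, y = expression(AUC["0-24h"] ~ "(h mg/L)"),
                  title = "Exposure variability between patients (IIV) and occasions (IOV)") +
    ggplot2::theme_bw()
}

#' Forecasted versus true dose distributions
#'
#' Histograms of the MIPD-forecasted doses (after the last occasion) and of
#' the true optimal doses across a simulated cohort.
#'
#' @param cohort a [run_mipd_cohort()] result.
#' @param n_occasions occasion count of the forecast shown (defaults to the
#'   last).
#' @return a ggplot object.
#' @export
plot_dose_distribution <- function(cohort,
                                   n_occasions = max(cohort$occasion)) {
  fc <- forecast_after(cohort, n_occasions)
  df <- dplyr::bind_rows(
    tibble::tibble(dose = fc$forecast_dose, which = "MIPD forecast"),
    tibble::tibble(dose = fc$true_dose, which = "True dose")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$dose))) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(~which, ncol = 1) +
    ggplot2::labs(x = "Dose (mg)", y = "Subjects") +
    ggplot2::theme_bw()
}

#' Prediction-error distributions by estimation model
#'
#' Box-style summary (median, 75\% box, 95\% whiskers) of the individual
#' dose prediction error per arm of a variant-comparison experiment.
#'
#' @param x result of [experiment_mipd_variant_comparison()].
#' @return a ggplot object.
#' @export
plot_prediction_error <- function(x) {
  s <- x$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$arm)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$p2.5, lower = .data$p12.5,
                   middle = .data$median, upper = .data$p87.5,
                   ymax = .data$p97.5),
      stat = "identity", width = 0.5
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Estimation model",
                  y = "Individual dose prediction error (%)") +
    ggplot2::theme_bw()
}

#' @export
autoplot.rif_experiment <- function(object, ...) {
  if (!is.null(object$aucs)) return(plot_occasion_aucs(object, ...))
  if (!is.null(object$arms)) return(plot_prediction_error(object))
  if (!is.null(object$cohort)) return(plot_dose_distribution(object$cohort))
  stop("no autoplot defined for this experiment", call. = FALSE)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
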