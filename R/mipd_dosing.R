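#' Time-varying Bayesian AUC target ranges
#'
#' Acceptable ranges of AUC_0-24h by day after the first dose, centred on
#' the exposure of the typical patient at 35 mg/kg and narrowing as
#' auto-induction develops. The bounds are the mid-points between the
#' typical exposures at 30/35 mg/kg (lower) and 35/40 mg/kg (upper).
#'
#' @return tibble with columns `day`, `lower`, `upper` (h mg/L).
#' @export
#' @examples
#' target_table()
target_table <- function() {
  tibble::tibble(
    day = c(1L, 7L, 14L, 28L, 56L),
    lower = c(342, 217, 189, 182, 181),
    upper = c(408, 259, 224, 215, 214)
  )
}

#' @rdname target_table
#' @param day day after first dose; must be one of the tabulated days.
#' @param table a target table.
#' @export
auc_target_range <- function(day, table = target_table()) {
  i <- match(day, table$day)
  if (is.na(i)) {
    stop("no AUC target tabulated for day ", day, call. = FALSE)
  }
  c(lower = table$lower[i], upper = table$upper[i])
}

#' Candidate dose grid
#'
#' Doses of 600-3,300 mg in 300-mg (tablet strength) increments.
#' @return numeric vector of doses, mg.
#' @export
dose_grid <- function() seq(600, 3300, by = 300)

#' Predicted AUC for every candidate dose
#'
#' Forecasts AUC_0-24h at the target day for each grid dose, using the
#' subject's estimated (or true) IIV etas with all occasion etas set to
#' zero - occasion variability is deliberately excluded from the forecast so
#' that one dose is predicted for all future occasions. Each candidate dose
#' is simulated as given once daily from day 1.
#'
#' @param params a [rif_params()] object (the model used for forecasting).
#' @param subject subject with `ffm`.
#' @param eta_iiv named length-6 IIV eta vector (EBEs or true etas).
#' @param target_day day after first dose at which the AUC is evaluated.
#' @param doses candidate doses, mg.
#' @param rtol,atol solver tolerances.
#' @return tibble with columns `dose` and `auc`, AUC strictly increasing in
#'   dose; doses whose simulation fails are dropped with a warning.
#' @export
predict_auc_grid <- function(params, subject, eta_iiv = zero_iiv(),
                             target_day = 14, doses = dose_grid(),
                             rtol = 1e-8, atol = 1e-10) {
  auc <- vapply(doses, function(d) {
    tryCatch(auc_0_24(params, subject, d, target_day, eta_iiv,
                      rtol = rtol, atol = atol),
             error = function(e) {
               warning("AUC simulation failed for dose ", d, " mg: ",
                       conditionMessage(e), call. = FALSE)
               NA_real_
             })
  }, numeric(1))
  tibble::tibble(dose = doses, auc = auc)[!is.na(auc), ]
}

#' Select the dose against an acceptable AUC range
#'
#' If at least one candidate dose yields an AUC inside the acceptable range,
#' the lowest such dose is chosen (safety rule). Otherwise the dose whose
#' AUC is closest to the range is chosen, ties broken toward the lower dose.
#'
#' @param auc_by_dose tibble with columns `dose` and `auc` (or a named
#'   numeric vector of AUCs with doses as names).
#' @param range `c(lower, upper)` acceptable AUC range, h mg/L.
#' @return selected dose, mg.
#' @export
#' @examples
#' select_dose(c(`1500` = 190, `1800` = 222), c(189, 224)) # 1500
select_dose <- function(auc_by_dose, range) {
  if (is.numeric(auc_by_dose) && !is.null(names(auc_by_dose))) {
    auc_by_dose <- tibble::tibble(dose = as.numeric(names(auc_by_dose)),
                                  auc = unname(auc_by_dose))
  }
  if (!nrow(auc_by_dose)) stop("empty dose grid", call. = FALSE)
  stopifnot(length(range) == 2, range[1] < range[2])
  within <- auc_by_dose$auc >= range[1] & auc_by_dose$auc <= range[2]
  if (any(within)) {
    return(min(auc_by_dose$dose[within]))
  }
  dist <- pmax(range[1] - auc_by_dose$auc, auc_by_dose$auc - range[2], 0)
  cand <- auc_by_dose$dose[dist == min(dist)]
  min(cand)
}

#' True optimal dose of a simulated subject
#'
#' The dose the MIPD algorithm would select if the subject's true IIV etas
#' were known: [select_dose()] applied to the AUC grid computed from the
#' true etas (occasion etas zero) at the day-14 target range.
#'
#' @inheritParams predict_auc_grid
#' @param target_day day of the target range (default 14).
#' @return dose in mg on the candidate grid.
#' @export
true_optimal_dose <- function(params, subject, eta_iiv = zero_iiv(),
                              target_day = 14, doses = dose_grid(),
                              rtol = 1e-8, atol = 1e-10) {
  g <- predict_auc_grid(params, subject, eta_iiv, target_day, doses,
                        rtol, atol)
  select_dose(g, auc_target_range(target_day))
}

## Deterministic sub-seed, kept well below 2^31.
sub_seed <- function(seed, i, k = 0) {
  (as.integer(seed) %% 100000L) * 20000L + 13L * as.integer(i) +
    3L * as.integer(k) + 1L
}

#' Run the iterative MIPD algorithm over a simulated cohort
#'
#' Simulates the full precision-dosing workflow: a virtual cohort is drawn
#' (covariates, true IIV etas, and per-occasion IOV etas under the truth
#' model, which always carries IOV); each subject starts on a weight-based
#' 35 mg/kg dose rounded to the tablet grid; at every sampling occasion
#' sparse concentrations (pre-dose, 2 h, 4 h) are simulated under the
#' current regimen with residual error and LLOQ censoring, the subject's
#' etas are re-estimated by MAP from all accumulated data under the chosen
#' estimation model (`params_est`: with or without IOV), and the dose for
#' the next target day is forecast from the IIV EBEs with occasion etas
#' zeroed. The dose changes at the first dosing time after each occasion.
#' Each subject's true optimal dose (from the true IIV etas at the day-14
#' target) is recorded for evaluation.
#'
#' @param n number of subjects.
#' @param params_true truth model used to simulate the cohort (must be the
#'   IOV-carrying variant for realistic occasion variability).
#' @param params_est model used for EBE estimation and dose forecasting.
#' @param occasion_days sampling-occasion days (default days 1 and 7).
#' @param mg_per_kg starting weight-based dose level.
#' @param seed integer seed; the cohort truth (covariates, etas) and the
#'   first-occasion observations are reproducible functions of it, so runs
#'   differing only in `params_est` share the same simulated truth.
#' @param lloq lower limit of quantification, mg/L.
#' @param sigma_log residual SD used when simulating observations.
#' @param offsets within-day sampling offsets, h relative to the dose.
#' @param n_starts,n_optimize,maxit MAP estimation settings, see
#'   [estimate_ebes()].
#' @param rtol,atol solver tolerances for estimation and forecasting.
#' @param keep_fits keep each cycle's `ebe_fit` in a list column.
#' @return a tibble of class `mipd_cohort` with one row per subject and
#'   occasion: `id`, `sex`, `wt`, `ffm`, `true_dose`, `occasion`, `day`,
#'   `dose_on_day` (dose administered at that occasion), `target_day`,
#'   `forecast_dose`, `objective`, `convergence`, `excluded` (estimation
#'   failure), and optionally `fit`.
#' @export
run_mipd_cohort <- function(n, params_true = rif_params("with_iov"),
                            params_est = params_true,
                            occasion_days = c(1, 7), mg_per_kg = 35,
                            seed = 1, lloq = 0.3,
                            sigma_log = params_true$sigma_log,
                            offsets = c(-5 / 60, 2, 4),
                            n_starts = 100, n_optimize = 2, maxit = 200,
                            rtol = 1e-5, atol = 1e-7, keep_fits = FALSE) {
  stopifnot(length(occasion_days) >= 1, !is.unsorted(occasion_days))
  occasion_days <- as.integer(occasion_days)
  covs <- sample_covariates(n, seed = sub_seed(seed, 0, 0))
  etas <- draw_etas(params_true, n, occasion_days,
                    seed = sub_seed(seed, 0, 1))
  K <- length(occasion_days)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    subj <- covs[i, ]
    eta_true <- etas$iiv[i, ]
    iov_true <- iov_slice(etas$iov, i)
    true_dose <- true_optimal_dose(params_true, subj, eta_true, 14)
    max_day <- max(occasion_days)
    dose_by_day <- rep(assign_initial_dose(subj$wt, mg_per_kg), max_day)
    data_obs <- NULL
    prev_eta <- NULL
    rows <- vector("list", K)
    excluded <- FALSE
    for (k in seq_len(K)) {
      d <- occasion_days[k]
      regimen <- tibble::tibble(time = 24 * (seq_len(d) - 1),
                                amt = dose_by_day[seq_len(d)])
      obs <- simulate_observations(
        params_true, subj, regimen,
        schedule = sampling_schedule(days = d, offsets = offsets),
        eta_iiv = eta_true,
        iov_etas = iov_true[rownames(iov_true) %in% as.character(occasion_days[1:k]), , drop = FALSE],
        sigma_log = sigma_log, lloq = lloq,
        seed = sub_seed(seed, i, k), id = subj$id
      )
      new_obs <- obs[obs$EVID == 0L, ]
      new_obs$OCC <- k
      data_obs <- dplyr::bind_rows(data_obs, new_obs)
      dataset <- dplyr::bind_rows(
        tibble::tibble(ID = subj$id, TIME = regimen$time, AMT = regimen$amt,
                       DV = NA_real_, EVID = 1L, MDV = 1L, BLQ = NA_integer_,
                       OCC = NA_integer_, SEX = subj$sex, WT = subj$wt,
                       FFM = subj$ffm),
        data_obs
      )
      target_day <- if (k < K) occasion_days[k + 1] else {
        tt <- target_table()
        tt$day[which(tt$day > d)[1]]
      }
      fit <- tryCatch(
        estimate_ebes(dataset, params_est,
                      occasion_days = occasion_days[1:k],
                      n_starts = n_starts, n_optimize = n_optimize,
                      prev_eta = prev_eta, seed = sub_seed(seed, i, 10 + k),
                      lloq = lloq, rtol = rtol, atol = atol, maxit = maxit),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        excluded <- TRUE
        rows[[k]] <- tibble::tibble(
          occasion = k, day = d, dose_on_day = dose_by_day[d],
          target_day = target_day, forecast_dose = NA_real_,
          objective = NA_real_, convergence = NA_integer_
        )
        if (keep_fits) rows[[k]]$fit <- list(NULL)
        next
      }
      prev_eta <- fit$eta
      ## dose selection at reference solver precision, like the true dose
      grid <- predict_auc_grid(params_est, subj, fit$eta_iiv, target_day)
      dnext <- select_dose(grid, auc_target_range(target_day))
      if (d < max_day) dose_by_day[(d + 1):max_day] <- dnext
      rows[[k]] <- tibble::tibble(
        occasion = k, day = d, dose_on_day = dose_by_day[d],
        target_day = target_day, forecast_dose = dnext,
        objective = fit$objective, convergence = fit$convergence
      )
      if (keep_fits) rows[[k]]$fit <- list(fit)
    }
    res[[i]] <- dplyr::bind_cols(
      tibble::tibble(id = subj$id, sex = subj$sex, wt = subj$wt,
                     ffm = subj$ffm, true_dose = true_dose,
                     excluded = excluded),
      dplyr::bind_rows(rows)
    )
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("mipd_cohort", class(out))
  attr(out, "occasion_days") <- occasion_days
  attr(out, "variant_est") <- params_est$variant
  attr(out, "seed") <- seed
  out
}

#' Per-subject dose forecasts after a given number of occasions
#'
#' Convenience accessor for a [run_mipd_cohort()] result: the forecasted and
#' true dose of every non-excluded subject after `n_occasions` sampling
#' occasions.
#'
#' @param cohort a `mipd_cohort` tibble.
#' @param n_occasions number of occasions the forecast is based on.
#' @return tibble with `id`, `true_dose`, `forecast_dose`, `error_pct`
#'   (individual prediction error).
#' @export
forecast_after <- function(cohort, n_occasions) {
  x <- cohort[cohort$occasion == n_occasions & !cohort$excluded, ]
  tibble::tibble(
    id = x$id, true_dose = x$true_dose, forecast_dose = x$forecast_dose,
    error_pct = individual_prediction_error(x$forecast_dose, x$true_dose)
  )
}
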