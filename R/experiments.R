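new_experiment <- function(name, ...) {
  structure(c(list(name = name), list(...)), class = "rif_experiment")
}

#' @export
print.rif_experiment <- function(x, ...) {
  cat("<rif_experiment>", x$name, "\n")
  for (nm in setdiff(names(x), c("name", "data", "subjects", "aucs",
                                 "arms", "cohorts"))) {
    v <- x[[nm]]
    if (is.numeric(v) && length(v) <= 4) {
      cat("  ", nm, ": ", paste(signif(v, 4), collapse = ", "), "\n", sep = "")
    } else if (inherits(v, "data.frame")) {
      cat("  ", nm, ": <", nrow(v), " x ", ncol(v), " tibble>\n", sep = "")
    }
  }
  invisible(x)
}

#' Occasion-level exposure variability in the typical patient
#'
#' Simulates the steady-state AUC_0-24h of the typical patient (male,
#' 53.9 kg, FFM 44.6 kg, 1,800 mg daily, steady state beyond day 24) for
#' many repeated sampling occasions with only occasion (IOV) etas active -
#' no IIV, no residual error - and summarises the spread as the
#' log-scale variability magnitude and an order-statistic 95\% prediction
#' interval. The induction history up to steady state is shared across
#' occasions; each occasion realises fresh etas for km, ka, MTT and F over
#' one dosing interval.
#'
#' @param n_occasions number of simulated occasions.
#' @param seed integer seed.
#' @param params a [rif_params()] object (the IOV-carrying variant).
#' @param dose daily dose, mg.
#' @param ss_day steady-state day whose dosing interval is evaluated.
#' @param rtol,atol solver tolerances.
#' @return a `rif_experiment` list with `aucs` (tibble `occasion`, `auc`),
#'   `magnitude` (percent), `pi` (95\% interval), `typical_auc` (zero-eta
#'   AUC of the same interval).
#' @export
experiment_iov_typical <- function(n_occasions = 1000, seed = 1,
                                   params = rif_params(), dose = 1800,
                                   ss_day = 25, rtol = 1e-8, atol = 1e-10) {
  set.seed(seed)
  subj <- typical_subject()
  t0 <- 24 * (ss_day - 1)
  regimen <- daily_regimen(dose, ss_day)
  base <- sim_core(params, subj$ffm, zero_iiv(), NULL, regimen, t0,
                   rtol, atol)
  init <- list(time = t0, state = base[1, ])
  eta <- matrix(rnorm(n_occasions * 4, 0,
                      rep(params$iov_sd, each = n_occasions)),
                nrow = n_occasions, dimnames = list(NULL, IOV_NAMES))
  aucs <- vapply(seq_len(n_occasions), function(j) {
    iov <- matrix(eta[j, ], nrow = 1,
                  dimnames = list(as.character(ss_day), IOV_NAMES))
    st <- sim_core(params, subj$ffm, zero_iiv(), iov, regimen,
                   c(t0, t0 + 24), rtol, atol, init = init)
    st[2, "cum_auc"] - st[1, "cum_auc"]
  }, numeric(1))
  st0 <- sim_core(params, subj$ffm, zero_iiv(), NULL, regimen,
                  c(t0, t0 + 24), rtol, atol, init = init)
  new_experiment(
    "occasion-level variability (typical patient, IOV only)",
    aucs = tibble::tibble(occasion = seq_len(n_occasions), auc = aucs),
    magnitude = variability_magnitude(aucs),
    pi = prediction_interval(aucs, 0.95),
    typical_auc = unname(st0[2, "cum_auc"] - st0[1, "cum_auc"]),
    n = n_occasions, dose = dose, ss_day = ss_day, seed = seed
  )
}

#' Between-patient exposure variability at the 35 mg/kg reference dose
#'
#' Simulates steady-state AUC_0-24h for a population with only IIV etas
#' active - no IOV, no residual error - and summarises the between-patient
#' spread. By default the random inter-individual PK variability is
#' isolated: every simulated patient shares the typical covariates and
#' receives the fixed reference dose of 1,800 mg (35 mg/kg in the typical
#' 53.9-kg patient), exactly mirroring the occasion-level experiment in
#' which only IOV etas act on the typical patient. Setting
#' `vary_covariates = TRUE` additionally samples covariates and doses each
#' subject per body weight, which adds weight-driven exposure spread on top
#' of the random IIV.
#'
#' @param n number of subjects.
#' @inheritParams experiment_iov_typical
#' @param dose fixed reference dose, mg (used when covariates are not
#'   varied).
#' @param vary_covariates sample per-subject covariates and dose
#'   `mg_per_kg` by weight instead of the fixed typical setup.
#' @param mg_per_kg weight-based dose level when `vary_covariates = TRUE`.
#' @return a `rif_experiment` with `subjects` (tibble `id`, `sex`, `wt`,
#'   `ffm`, `dose`, `auc`), `magnitude`, `pi`.
#' @export
experiment_iiv_population <- function(n = 1000, seed = 1,
                                      params = rif_params(), dose = 1800,
                                      vary_covariates = FALSE,
                                      mg_per_kg = 35, ss_day = 25,
                                      rtol = 1e-8, atol = 1e-10) {
  if (vary_covariates) {
    covs <- sample_covariates(n, seed = sub_seed(seed, 0, 0))
    dose_i <- covs$wt * mg_per_kg
  } else {
    covs <- dplyr::mutate(typical_subject()[rep(1, n), ], id = seq_len(n))
    dose_i <- rep(dose, n)
  }
  etas <- draw_etas(params, n, integer(0), seed = sub_seed(seed, 0, 1))
  aucs <- vapply(seq_len(n), function(i) {
    auc_0_24(params, covs[i, ], dose_i[i], ss_day, etas$iiv[i, ],
             rtol = rtol, atol = atol)
  }, numeric(1))
  new_experiment(
    "between-patient variability (IIV only)",
    subjects = dplyr::mutate(covs, dose = dose_i, auc = aucs),
    magnitude = variability_magnitude(aucs),
    pi = prediction_interval(aucs, 0.95),
    n = n, ss_day = ss_day, seed = seed
  )
}

#' Population exposure with and without occasion variability
#'
#' Simulates per-dose-level cohorts and contrasts the AUC_0-24h
#' distribution when per-occasion IOV etas are included with the
#' distribution from the same subjects (same IIV etas) when IOV is fixed to
#' zero. Occasion etas are drawn for the sampling-visit days; the per-day
#' AUC is evaluated at each requested day.
#'
#' @param n subjects per dose level.
#' @param dose_levels weight-based dose levels, mg/kg.
#' @param days evaluation days.
#' @param occasion_days visit days carrying occasion etas.
#' @inheritParams experiment_iov_typical
#' @return a `rif_experiment` with `data` (long tibble: `dose_level`, `id`,
#'   `day`, `auc_iiv`, `auc_iov`) and `summary` (per level and day: median
#'   and 95\% PI of both arms, plus the median and 95\% PI of the
#'   per-subject deviation).
#' @export
experiment_population_exposure <- function(n = 1000,
                                           dose_levels = c(10, 20, 25, 30, 35),
                                           days = c(1, 7, 14),
                                           occasion_days = c(1, 7, 14),
                                           seed = 1, params = rif_params(),
                                           rtol = 1e-8, atol = 1e-10) {
  out <- vector("list", length(dose_levels))
  for (li in seq_along(dose_levels)) {
    lev <- dose_levels[li]
    covs <- sample_covariates(n, seed = sub_seed(seed, li, 0))
    etas <- draw_etas(params, n, occasion_days, seed = sub_seed(seed, li, 1))
    dose <- covs$wt * lev
    res <- lapply(seq_len(n), function(i) {
      a_iiv <- auc_0_24(params, covs[i, ], dose[i], days, etas$iiv[i, ],
                        rtol = rtol, atol = atol)
      a_iov <- auc_0_24(params, covs[i, ], dose[i], days, etas$iiv[i, ],
                        iov_etas = iov_slice(etas$iov, i),
                        rtol = rtol, atol = atol)
      tibble::tibble(dose_level = lev, id = i, day = days,
                     auc_iiv = a_iiv, auc_iov = a_iov)
    })
    out[[li]] <- dplyr::bind_rows(res)
  }
  data <- dplyr::bind_rows(out)
  summary <- data |>
    dplyr::group_by(.data$dose_level, .data$day) |>
    dplyr::summarise(
      median_iiv = median(.data$auc_iiv),
      iiv_lo = prediction_interval(.data$auc_iiv)[1],
      iiv_hi = prediction_interval(.data$auc_iiv)[2],
      median_iov = median(.data$auc_iov),
      iov_lo = prediction_interval(.data$auc_iov)[1],
      iov_hi = prediction_interval(.data$auc_iov)[2],
      median_dev = median(.data$auc_iov - .data$auc_iiv),
      dev_lo = prediction_interval(.data$auc_iov - .data$auc_iiv)[1],
      dev_hi = prediction_interval(.data$auc_iov - .data$auc_iiv)[2],
      .groups = "drop"
    )
  new_experiment("population exposure with and without IOV",
                 data = data, summary = summary, n = n, seed = seed)
}

#' MIPD prediction error with an IOV-aware versus IOV-ignoring model
#'
#' Runs the full MIPD cycle on one simulated truth cohort twice: once
#' estimating and forecasting with the IOV-carrying model and once with the
#' mis-specified re-estimated model in which IOV was fixed to zero. Both
#' arms share the same simulated truth (covariates, etas, first-occasion
#' observations). Reports the per-subject dose prediction error after the
#' final occasion together with its median and 75\%/95\% prediction
#' intervals per arm.
#'
#' @param n number of subjects.
#' @param occasion_days sampling occasions (default days 1 and 7).
#' @param seed integer seed.
#' @param params_true truth model.
#' @param params_noiov the IOV-ignoring estimation model.
#' @param ... further arguments passed to [run_mipd_cohort()].
#' @return a `rif_experiment` with `arms` (named list of per-subject error
#'   tibbles), `summary` (per arm: median, 12.5/87.5th and 2.5/97.5th
#'   percentiles of the prediction error), and `cohorts` (the two
#'   `mipd_cohort` objects).
#' @export
experiment_mipd_variant_comparison <- function(n = 1000,
                                               occasion_days = c(1, 7),
                                               seed = 1,
                                               params_true = rif_params("with_iov"),
                                               params_noiov = rif_params("no_iov"),
                                               ...) {
  run_iov <- run_mipd_cohort(n, params_true, params_true,
                             occasion_days = occasion_days, seed = seed, ...)
  run_no <- run_mipd_cohort(n, params_true, params_noiov,
                            occasion_days = occasion_days, seed = seed, ...)
  k <- length(occasion_days)
  arms <- list(with_iov = forecast_after(run_iov, k),
               no_iov = forecast_after(run_no, k))
  summary <- dplyr::bind_rows(lapply(names(arms), function(a) {
    e <- arms[[a]]$error_pct
    tibble::tibble(
      arm = a, n = length(e), median = median(e),
      p12.5 = prediction_interval(e, 0.75)[1],
      p87.5 = prediction_interval(e, 0.75)[2],
      p2.5 = prediction_interval(e, 0.95)[1],
      p97.5 = prediction_interval(e, 0.95)[2]
    )
  }))
  new_experiment("MIPD prediction error: IOV-aware vs IOV-ignoring model",
                 arms = arms, summary = summary,
                 cohorts = list(with_iov = run_iov, no_iov = run_no),
                 n = n, seed = seed)
}

#' Dose-prediction accuracy by number of sampling occasions
#'
#' Runs the MIPD cycle with the IOV-aware model across all scheduled
#' occasions and evaluates the bias ([mape()]) and imprecision ([rrmse()])
#' of the dose forecast after one, two, ... occasions against each
#' subject's true dose, overall and stratified by true dose, with paired
#' bootstrap confidence intervals for the change between consecutive
#' occasion counts.
#'
#' @param n number of subjects.
#' @param occasion_days sampling occasions (default days 1, 7 and 14).
#' @param seed integer seed.
#' @param params_true truth and estimation model.
#' @param B bootstrap resamples for the difference CIs.
#' @param ... further arguments passed to [run_mipd_cohort()].
#' @return a `rif_experiment` with `cohort` (the `mipd_cohort`), `overall`
#'   (tibble: `n_occasions`, `rrmse`, `mape`, `n`), `by_dose` (the same
#'   stratified by true dose) and `differences` (metric changes between
#'   consecutive occasion counts with CIs and significance flags).
#' @export
experiment_occasion_count <- function(n = 1000, occasion_days = c(1, 7, 14),
                                      seed = 1,
                                      params_true = rif_params("with_iov"),
                                      B = 2000, ...) {
  run <- run_mipd_cohort(n, params_true, params_true,
                         occasion_days = occasion_days, seed = seed, ...)
  K <- length(occasion_days)
  fc <- lapply(seq_len(K), forecast_after, cohort = run)
  overall <- dplyr::bind_rows(lapply(seq_len(K), function(k) {
    tibble::tibble(n_occasions = k,
                   rrmse = rrmse(fc[[k]]$forecast_dose, fc[[k]]$true_dose),
                   mape = mape(fc[[k]]$forecast_dose, fc[[k]]$true_dose),
                   n = nrow(fc[[k]]))
  }))
  by_dose <- dplyr::bind_rows(lapply(seq_len(K), function(k) {
    fc[[k]] |>
      dplyr::group_by(true_dose = .data$true_dose) |>
      dplyr::summarise(n_occasions = k,
                       rrmse = rrmse(.data$forecast_dose, .data$true_dose),
                       mape = mape(.data$forecast_dose, .data$true_dose),
                       n = dplyr::n(), .groups = "drop")
  }))
  differences <- NULL
  if (K >= 2) {
    differences <- dplyr::bind_rows(lapply(seq_len(K - 1), function(k) {
      pair <- dplyr::inner_join(fc[[k]], fc[[k + 1]], by = c("id", "true_dose"),
                                suffix = c("_a", "_b"))
      dplyr::bind_rows(lapply(c("rrmse", "mape"), function(m) {
        ci <- paired_difference_ci(m, pair$forecast_dose_a,
                                   pair$forecast_dose_b, pair$true_dose,
                                   B = B, seed = sub_seed(seed, k, 99))
        dplyr::mutate(ci, metric = m,
                      comparison = paste0(k, " vs ", k + 1), .before = 1)
      }))
    }))
  }
  new_experiment("dose-prediction accuracy by number of occasions",
                 cohort = run, overall = overall, by_dose = by_dose,
                 differences = differences, n = n, seed = seed)
}
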