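## Order conventions for random-effect vectors, used throughout the package.
IIV_NAMES <- c("vmax", "km", "v", "ka", "mtt", "nn")
IOV_NAMES <- c("km", "ka", "mtt", "f")

zero_iiv <- function() stats::setNames(numeric(6), IIV_NAMES)
zero_iov <- function() stats::setNames(numeric(4), IOV_NAMES)

#' The typical patient of the study population
#'
#' A male patient with a body weight of 53.9 kg and a fat-free mass of
#' 44.6 kg, receiving 35 mg/kg (1,800 mg) rifampicin; used for the
#' occasion-level variability experiment and as the reference individual.
#'
#' @return a one-row tibble with columns `id`, `sex`, `wt`, `ffm`.
#' @export
typical_subject <- function() {
  tibble::tibble(id = 1L, sex = "male", wt = 53.9, ffm = 44.6)
}

as_subject <- function(subject) {
  s <- as.list(subject)
  if (is.null(s$ffm) || is.null(s$wt)) {
    stop("a subject needs 'wt' and 'ffm' fields", call. = FALSE)
  }
  stopifnot(s$wt > 0, s$ffm > 0, s$ffm < s$wt)
  s
}

#' Dose-dependent relative bioavailability
#'
#' Relative bioavailability F rises nonlinearly with dose above 450 mg
#' following a saturable (Emax-type) function of the dose excess over
#' 450 mg; below 450 mg it is fixed at `f450` (assumed 1 for lack of data).
#' A per-occasion log-scale deviation `eta_f` acts multiplicatively.
#'
#' @param dose dose in mg (vectorised).
#' @param params a [rif_params()] object.
#' @param eta_f log-scale occasion deviation on F (default 0).
#' @return F, dimensionless, non-decreasing in dose.
#' @export
#' @examples
#' bioavailability(c(450, 1800), rif_params())
bioavailability <- function(dose, params = rif_params(), eta_f = 0) {
  if (any(dose < 0)) stop("dose must be non-negative", call. = FALSE)
  base <- ifelse(dose <= 450, params$f450,
                 params$f450 *
                   (1 + params$fmax * (dose - 450) / (params$ed50 + (dose - 450))))
  base * exp(eta_f)
}

#' Concentration-dependent apparent clearance
#'
#' Michaelis-Menten apparent clearance CL = Vmax / (km + Cp): clearance
#' falls with rising plasma concentration as elimination (attributed to
#' saturable biliary efflux) approaches its capacity `Vmax`.
#'
#' @param cp plasma concentration, mg/L (vectorised, >= 0).
#' @param vmax maximal elimination rate, mg/h (> 0).
#' @param km concentration of half-maximal elimination, mg/L (> 0).
#' @return apparent clearance, L/h; strictly decreasing in `cp`.
#' @export
mm_clearance <- function(cp, vmax, km) {
  if (any(cp < 0)) stop("cp must be non-negative", call. = FALSE)
  stopifnot(vmax > 0, km > 0)
  vmax / (km + cp)
}

#' Transit-compartment absorption input rate
#'
#' Analytic input rate of a transit-compartment absorption chain with mean
#' transit time `mtt` and a possibly non-integer number of transit
#' compartments `nn`: a gamma-density pulse
#' `F * dose * ktr * (ktr t)^nn * exp(-ktr t) / Gamma(nn + 1)` with
#' `ktr = (nn + 1) / mtt`, which integrates to `F * dose` over `[0, Inf)`.
#' The closed form is the only definition available for non-integer `nn`;
#' multiple doses superpose.
#'
#' @param t hours since the dose (vectorised, >= 0).
#' @param dose_amount dose in mg.
#' @param f relative bioavailability applied to this dose.
#' @param mtt mean transit time, h (> 0).
#' @param nn number of transit compartments (> 0, non-integer allowed).
#' @return input rate into the absorption compartment, mg/h.
#' @export
transit_input_rate <- function(t, dose_amount, f, mtt, nn) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  stopifnot(mtt > 0, nn > 0)
  ktr <- (nn + 1) / mtt
  lt <- ifelse(t > 0, nn * log(ktr * t) - ktr * t - lgamma(nn + 1), -Inf)
  ifelse(is.finite(lt), f * dose_amount * ktr * exp(pmax(lt, -700)), 0)
}

individual_params <- function(params, ffm, eta_iiv = zero_iiv()) {
  sz <- ffm / params$reference_size
  list(
    vmax = params$vmax * sz^params$alloexp_vmax * exp(eta_iiv[["vmax"]]),
    km   = params$km * exp(eta_iiv[["km"]]),
    v    = params$v * sz^params$alloexp_v * exp(eta_iiv[["v"]]),
    ka   = params$ka * exp(eta_iiv[["ka"]]),
    mtt  = params$mtt * exp(eta_iiv[["mtt"]]),
    nn   = params$nn * exp(eta_iiv[["nn"]])
  )
}

#' Structural model right-hand side (reference implementation)
#'
#' Derivatives of the structural model state at time `t`: depot amount with
#' analytic transit input and first-order outflow `ka`, central amount with
#' Michaelis-Menten elimination scaled by the enzyme pool, enzyme turnover
#' with concentration-stimulated production (auto-induction), plus the two
#' augmented bookkeeping states (cumulative AUC and eliminated mass). This
#' plain-R version mirrors the compiled integrator's right-hand side and is
#' the one used with external ODE solvers in cross-checks.
#'
#' @param state named vector `c(depot, central, enz, cum_auc, cum_elim)`.
#' @param t time, h since first dose.
#' @param params a [rif_params()] object.
#' @param subject subject with `ffm` (see [typical_subject()]).
#' @param eta_iiv named length-6 log-scale IIV vector.
#' @param eta_iov named length-4 log-scale IOV vector in force at `t`.
#' @param regimen tibble with columns `time` (h) and `amt` (mg).
#' @return named vector of derivatives.
#' @export
pk_rhs <- function(state, t, params = rif_params(),
                   subject = typical_subject(),
                   eta_iiv = zero_iiv(), eta_iov = zero_iov(),
                   regimen = daily_regimen(0, 1)) {
  s <- as_subject(subject)
  ip <- individual_params(params, s$ffm, eta_iiv)
  if (state[["enz"]] <= 0) stop("enzyme pool must stay positive", call. = FALSE)
  km <- ip$km * exp(eta_iov[["km"]])
  ka <- ip$ka * exp(eta_iov[["ka"]])
  mtt <- ip$mtt * exp(eta_iov[["mtt"]])
  cp <- max(state[["central"]] / ip$v, 0)
  past <- regimen[regimen$time < t & regimen$amt > 0, , drop = FALSE]
  inp <- 0
  if (nrow(past)) {
    fs <- bioavailability(past$amt, params, eta_iov[["f"]])
    inp <- sum(vapply(seq_len(nrow(past)), function(i) {
      transit_input_rate(t - past$time[i], past$amt[i], fs[i], mtt, ip$nn)
    }, numeric(1)))
  }
  elim <- ip$vmax * state[["enz"]] * cp / (km + cp)
  d <- c(
    depot = inp - ka * state[["depot"]],
    central = ka * state[["depot"]] - elim,
    enz = params$kenz * (1 + params$emax_enz * cp / (params$ec50_enz + cp)) -
      params$kenz * state[["enz"]],
    cum_auc = cp,
    cum_elim = elim
  )
  if (any(!is.finite(d))) {
    stop("non-finite derivative at t = ", t, call. = FALSE)
  }
  d
}

#' Once-daily dosing regimen
#'
#' @param dose dose per administration, mg; either a scalar or one amount
#'   per day.
#' @param n_days number of dosing days.
#' @param interval dosing interval, h.
#' @return tibble with columns `time` (h since first dose) and `amt` (mg).
#' @export
daily_regimen <- function(dose, n_days, interval = 24) {
  tibble::tibble(time = interval * (seq_len(n_days) - 1),
                 amt = rep_len(dose, n_days))
}

## Normalise occasion etas to a matrix with one row per occasion day
## (rownames = day index as character, columns IOV_NAMES). NULL -> no IOV.
as_iov_matrix <- function(iov_etas) {
  if (is.null(iov_etas)) return(NULL)
  if (is.list(iov_etas) && !is.data.frame(iov_etas)) {
    if (!length(iov_etas)) return(NULL)
    m <- do.call(rbind, iov_etas)
    rownames(m) <- names(iov_etas)
    iov_etas <- m
  }
  stopifnot(is.matrix(iov_etas), ncol(iov_etas) == 4,
            !is.null(rownames(iov_etas)))
  colnames(iov_etas) <- IOV_NAMES
  iov_etas
}

## Core solver call: returns matrix of the 5 states at out_times.
## init: optional list(time=, state=) to resume from a stored state.
sim_core <- function(params, ffm, eta_iiv, iov_etas, regimen, out_times,
                     rtol = 1e-8, atol = 1e-10, init = NULL) {
  ip <- individual_params(params, ffm, eta_iiv)
  iov <- as_iov_matrix(iov_etas)
  regimen <- regimen[regimen$amt > 0, , drop = FALSE]
  t0 <- if (is.null(init)) 0 else init$time
  horizon <- max(out_times, t0)
  nday <- max(1L, as.integer(ceiling((horizon + 1e-9) / 24)))
  km_mult <- rep(1, nday)
  ka_mult <- rep(1, nday)
  eta_days <- integer(0)
  if (!is.null(iov)) {
    eta_days <- as.integer(rownames(iov))
    for (i in seq_along(eta_days)) {
      d <- eta_days[i]
      if (d >= 1 && d <= nday) {
        km_mult[d] <- exp(iov[i, "km"])
        ka_mult[d] <- exp(iov[i, "ka"])
      }
    }
  }
  ## per-dose realisations: day of administration decides the occasion etas
  dose_day <- as.integer(floor(regimen$time / 24)) + 1L
  d_mtt <- rep(ip$mtt, nrow(regimen))
  d_f <- bioavailability(regimen$amt, params)
  if (!is.null(iov)) {
    idx <- match(dose_day, eta_days)
    hit <- which(!is.na(idx))
    if (length(hit)) {
      d_mtt[hit] <- d_mtt[hit] * exp(iov[idx[hit], "mtt"])
      d_f[hit] <- d_f[hit] * exp(iov[idx[hit], "f"])
    }
  }
  d_ktr <- (ip$nn + 1) / d_mtt
  d_mass <- d_f * regimen$amt

  ## stop points: dose times (hard restarts), boundaries of days carrying
  ## occasion etas (rhs discontinuities), and the requested output times
  bound <- if (length(eta_days)) sort(unique(c(24 * (eta_days - 1), 24 * eta_days))) else numeric(0)
  stops <- sort(unique(c(t0, regimen$time, bound, out_times)))
  stops <- stops[stops >= t0 & stops <= horizon]
  hard <- stops %in% regimen$time | stops %in% bound
  y0 <- if (is.null(init)) c(0, 0, 1, 0, 0) else init$state
  theta <- c(ip$vmax, ip$km, ip$v, ip$ka,
             params$emax_enz, params$ec50_enz, params$kenz, ip$nn)
  out <- .Call(C_rif_sim, as.numeric(stops), as.integer(hard),
               as.numeric(y0), as.numeric(theta),
               as.numeric(regimen$time), as.numeric(d_mass),
               as.numeric(d_ktr), km_mult, ka_mult,
               as.numeric(c(rtol, atol)))
  res <- out[match(out_times, stops), , drop = FALSE]
  colnames(res) <- c("depot", "central", "enz", "cum_auc", "cum_elim")
  res
}

#' Simulate a noise-free concentration profile
#'
#' Deterministic plasma-concentration, enzyme-pool and cumulative-AUC
#' trajectories for one individual under a dosing regimen, with allometric
#' FFM scaling of Vmax (exponent 0.75) and V (exponent 1), log-normal IIV
#' deviations and, optionally, per-occasion IOV deviations. Occasion etas
#' apply to the 24-h dosing interval(s) of their visit day; all other days
#' use typical (zero) occasion deviations.
#'
#' @param params a [rif_params()] object.
#' @param subject subject with `ffm` (one-row tibble or list).
#' @param regimen dosing tibble (`time`, `amt`), e.g. [daily_regimen()].
#' @param times output times, h since first dose (negative times allowed and
#'   reported as drug-free).
#' @param eta_iiv named length-6 log-scale IIV vector (default all zero).
#' @param iov_etas occasion deviations: a matrix with one row per occasion
#'   day (rownames = day index) and columns `km`, `ka`, `mtt`, `f`, or a
#'   named list of length-4 vectors; `NULL` for none.
#' @param rtol,atol relative/absolute solver tolerances.
#' @return tibble with columns `time`, `conc` (mg/L), `enz`, `cum_auc`
#'   (h mg/L), `depot`, `central`, `cum_elim` (mg).
#' @export
#' @examples
#' simulate_profile(rif_params(), typical_subject(),
#'                  daily_regimen(1800, 2), times = c(1, 2, 4, 24, 26))
simulate_profile <- function(params, subject, regimen, times,
                             eta_iiv = zero_iiv(), iov_etas = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  s <- as_subject(subject)
  pos <- times >= 0
  res <- matrix(rep(c(0, 0, 1, 0, 0), each = length(times)),
                nrow = length(times))
  colnames(res) <- c("depot", "central", "enz", "cum_auc", "cum_elim")
  if (any(pos) && nrow(regimen[regimen$amt > 0, ]) > 0) {
    res[pos, ] <- sim_core(params, s$ffm, eta_iiv, iov_etas, regimen,
                           times[pos], rtol, atol)
  }
  ip <- individual_params(params, s$ffm, eta_iiv)
  tibble::tibble(
    time = times,
    conc = pmax(res[, "central"], 0) / ip$v,
    enz = res[, "enz"],
    cum_auc = res[, "cum_auc"],
    depot = res[, "depot"],
    central = res[, "central"],
    cum_elim = res[, "cum_elim"]
  )
}

#' AUC over a 24-h dosing interval under once-daily dosing
#'
#' The area under the plasma concentration-time curve over the dosing
#' interval of a given treatment day, with the dose administered once daily
#' from day 1. Computed from the augmented cumulative-integral ODE state,
#' not by quadrature on a concentration grid.
#'
#' @inheritParams simulate_profile
#' @param dose daily dose, mg.
#' @param day treatment day (vectorised); day 1 starts at the first dose.
#' @return AUC_0-24h per requested day, h mg/L. Strictly increasing and
#'   more-than-proportional in dose at typical parameters (dose-dependent
#'   bioavailability plus saturable elimination).
#' @export
#' @examples
#' auc_0_24(rif_params(), typical_subject(), dose = 1800, day = c(1, 7, 14))
auc_0_24 <- function(params, subject, dose, day, eta_iiv = zero_iiv(),
                     iov_etas = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(all(day >= 1), dose >= 0)
  if (dose == 0) return(rep(0, length(day)))
  s <- as_subject(subject)
  nd <- max(day)
  tt <- sort(unique(c(24 * (day - 1), 24 * day)))
  res <- sim_core(params, s$ffm, eta_iiv, iov_etas, daily_regimen(dose, nd),
                  tt, rtol, atol)
  cum <- res[, "cum_auc"]
  cum[match(24 * day, tt)] - cum[match(24 * (day - 1), tt)]
}
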