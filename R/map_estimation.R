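## Occasion visit day of each observation occasion in a dataset: the day
## whose dosing interval contains the bulk of the occasion's samples.
infer_occasion_days <- function(data) {
  obs <- data[data$EVID == 0L & !is.na(data$OCC), ]
  if (!nrow(obs)) return(integer(0))
  vapply(split(obs$TIME, obs$OCC),
         function(tt) as.integer(floor(max(tt) / 24)) + 1L, integer(1))
}

## Precompute everything the optimiser needs; returns a closure over the
## packed eta vector c(iiv[6], iov_occ1[4], iov_occ2[4], ...).
make_map_objective <- function(data, params, occasion_days = NULL,
                               lloq = 0.3, penalty = 1e6,
                               rtol = 1e-5, atol = 1e-7) {
  obs <- data[data$EVID == 0L, ]
  if (!nrow(obs)) stop("dataset contains no observations", call. = FALSE)
  regimen <- tibble::tibble(time = data$TIME[data$EVID == 1L],
                            amt = data$AMT[data$EVID == 1L])
  if (is.null(occasion_days)) occasion_days <- infer_occasion_days(data)
  include_iov <- any(params$iov_sd > 0)
  n_occ <- if (include_iov) length(occasion_days) else 0L
  ffm <- data$FFM[1]
  Om <- iiv_cov(params)
  Om_inv <- solve(Om)
  ld_iiv <- determinant(Om, logarithm = TRUE)$modulus + 6 * log(2 * pi)
  iov_var <- params$iov_sd^2
  ld_iov <- if (include_iov) sum(log(2 * pi * iov_var)) else 0
  sig <- params$sigma_log
  t_obs <- obs$TIME
  pos <- t_obs >= 0
  blq <- obs$BLQ == 1L
  log_dv <- ifelse(blq, NA_real_, log(obs$DV))
  log_lloq <- ifelse(blq, log(obs$DV), NA_real_) # BLQ rows carry the LLOQ

  ## precomputed fast simulation path: everything that does not depend on
  ## eta is set up once, so one objective evaluation is a single .Call plus
  ## vectorised arithmetic
  rt <- regimen$time[regimen$amt > 0]
  ra <- regimen$amt[regimen$amt > 0]
  f_base <- bioavailability(ra, params)
  dose_occ <- match(as.integer(floor(rt / 24)) + 1L, occasion_days)
  out_t <- sort(unique(t_obs[pos]))
  horizon <- max(out_t, rt, 24)
  nday <- max(1L, as.integer(ceiling((horizon + 1e-9) / 24)))
  occ_in <- occasion_days[occasion_days <= nday]
  bound <- sort(unique(c(24 * (occ_in - 1), 24 * occ_in)))
  bound <- bound[bound <= horizon]
  stops <- sort(unique(c(0, rt, bound, out_t)))
  hard <- stops %in% rt | stops %in% bound
  idx_stop <- match(out_t, stops)
  idx_obs <- match(t_obs[pos], out_t)
  sz <- ffm / params$reference_size
  vmax_base <- params$vmax * sz^params$alloexp_vmax
  v_base <- params$v * sz^params$alloexp_v
  y0 <- c(0, 0, 1, 0, 0)
  tol <- c(rtol, atol)
  one <- rep(1, nday)

  sim_pred <- function(eta) {
    theta <- c(vmax_base * exp(eta[1]), params$km * exp(eta[2]),
               v_base * exp(eta[3]), params$ka * exp(eta[4]),
               params$emax_enz, params$ec50_enz, params$kenz,
               params$nn * exp(eta[6]))
    km_mult <- one
    ka_mult <- one
    mtt_i <- params$mtt * exp(eta[5])
    d_mtt <- rep(mtt_i, length(rt))
    mass <- f_base * ra
    if (n_occ > 0) {
      e_iov <- matrix(eta[-(1:6)], nrow = n_occ, byrow = TRUE)
      km_mult[occ_in] <- exp(e_iov[match(occ_in, occasion_days), 1])
      ka_mult[occ_in] <- exp(e_iov[match(occ_in, occasion_days), 2])
      hit <- !is.na(dose_occ)
      d_mtt[hit] <- d_mtt[hit] * exp(e_iov[dose_occ[hit], 3])
      mass[hit] <- mass[hit] * exp(e_iov[dose_occ[hit], 4])
    }
    st <- .Call(C_rif_sim, stops, as.integer(hard), y0, theta, rt, mass,
                (theta[8] + 1) / d_mtt, km_mult, ka_mult, tol)
    pred <- numeric(length(t_obs))
    pred[pos] <- pmax(st[idx_stop, 2], 0)[idx_obs] / theta[3]
    pred
  }

  function(eta) {
    pred <- sim_pred(eta)
    ll <- 0
    ## quantified observations: normal density of log(DV) around log(pred)
    q <- !blq
    if (any(q)) {
      bad <- q & pred <= 0
      if (any(bad)) ll <- ll + penalty * sum(bad)
      ok <- q & pred > 0
      if (any(ok)) {
        r <- (log_dv[ok] - log(pred[ok])) / sig
        ll <- ll + sum(r^2) + sum(ok) * log(2 * pi * sig^2)
      }
    }
    ## censored observations: M3 cumulative-probability term
    if (any(blq)) {
      z <- ifelse(pred[blq] > 1e-12,
                  (log_lloq[blq] - log(pmax(pred[blq], 1e-300))) / sig,
                  Inf)
      ll <- ll - 2 * sum(pnorm(z, log.p = TRUE))
    }
    ## prior on the random effects
    e_iiv <- eta[1:6]
    ll <- ll + drop(e_iiv %*% Om_inv %*% e_iiv) + as.numeric(ld_iiv)
    if (n_occ > 0) {
      e_iov <- matrix(eta[-(1:6)], nrow = n_occ, byrow = TRUE)
      ll <- ll + sum(sweep(e_iov^2, 2, iov_var, "/")) + n_occ * ld_iov
    }
    ll
  }
}

#' MAP objective: -2 log posterior of the random effects
#'
#' The objective minimised in empirical Bayes (MAP) estimation: for
#' quantified observations, the normal -2 log density of `log(DV)` with mean
#' `log(pred)` and SD `sigma_log`; for censored (BLQ) records, the M3
#' contribution `-2 log Phi((log LLOQ - log pred) / sigma_log)`; plus the
#' multivariate-normal -2 log prior on all etas (IIV with the full
#' covariance including the Vmax-km correlation, occasion etas with the
#' diagonal IOV variances). Under the `no_iov` parameter variant the eta
#' vector has no occasion components. Non-positive predictions at a
#' quantified record contribute a large configurable penalty rather than
#' failing.
#'
#' @param eta packed eta vector: 6 IIV components (vmax, km, v, ka, mtt, nn)
#'   followed by 4 occasion components (km, ka, mtt, f) per occasion when
#'   the parameter set carries IOV.
#' @param data NONMEM-style dataset (one subject) as produced by
#'   [simulate_observations()].
#' @param params a [rif_params()] object.
#' @param occasion_days visit days of the occasions present in `data`;
#'   inferred from the data when `NULL`.
#' @param lloq lower limit of quantification, mg/L (used only for records
#'   not already flagged).
#' @param penalty objective penalty per non-positive prediction at a
#'   quantified record.
#' @param rtol,atol solver tolerances for the inner simulations.
#' @return -2 log posterior (up to the marginal-likelihood constant).
#' @export
map_objective <- function(eta, data, params, occasion_days = NULL,
                          lloq = 0.3, penalty = 1e6,
                          rtol = 1e-5, atol = 1e-7) {
  f <- make_map_objective(data, params, occasion_days, lloq, penalty,
                          rtol, atol)
  f(eta)
}

fd_gradient <- function(fn, x, f0 = NULL, h = 1e-5) {
  if (is.null(f0)) f0 <- fn(x)
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x
    xi[i] <- xi[i] + h
    g[i] <- (fn(xi) - f0) / h
  }
  g
}

#' Empirical Bayes (MAP) estimation of individual random effects
#'
#' Minimises [map_objective()] over the packed eta vector with a bounded
#' quasi-Newton method (L-BFGS-B, etas bounded to +/- 5 prior SDs) using a
#' multi-start initialisation scheme: the objective is evaluated at
#' `n_starts` candidate initial vectors - zeros, the previous cycle's
#' estimate when supplied, and random draws from the prior - and full
#' optimisations are run from the `n_optimize` most promising candidates
#' (the zero vector is always among them, so enlarging the candidate set
#' can only improve the returned minimum). The lowest-objective solution is
#' returned.
#'
#' @inheritParams map_objective
#' @param n_starts number of candidate initialisations (>= 1).
#' @param n_optimize number of candidates from which a full optimisation is
#'   run (the zero start plus the best `n_optimize - 1` others).
#' @param prev_eta optional packed eta vector from the previous estimation
#'   cycle, added to the candidate set (padded with zeros for occasions it
#'   does not cover).
#' @param seed optional integer seed for the random candidate draws.
#' @param maxit maximum optimiser iterations per start.
#' @return an object of class `ebe_fit`: list with `eta_iiv` (named
#'   length-6), `eta_iov` (matrix occasions x 4, or `NULL`), `eta` (packed),
#'   `objective`, `convergence` (0 = converged), `n_starts`,
#'   `candidate_objectives`, `occasion_days`, `n_obs`, `variant`.
#' @export
estimate_ebes <- function(data, params, occasion_days = NULL, n_starts = 100,
                          n_optimize = 2, prev_eta = NULL, seed = NULL,
                          lloq = 0.3, penalty = 1e6,
                          rtol = 1e-5, atol = 1e-7, maxit = 200) {
  if (!nrow(data[data$EVID == 0L, ])) {
    stop("at least one observation is required", call. = FALSE)
  }
  stopifnot(n_starts >= 1, n_optimize >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(occasion_days)) occasion_days <- infer_occasion_days(data)
  include_iov <- any(params$iov_sd > 0)
  n_occ <- if (include_iov) length(occasion_days) else 0L
  npar <- 6L + 4L * n_occ
  fn <- make_map_objective(data, params, occasion_days, lloq, penalty,
                           rtol, atol)
  prior_sd <- c(params$iiv_sd, rep(params$iov_sd, n_occ))
  bounds <- 5 * pmax(prior_sd, 1e-3)

  ## candidate initialisations
  cand <- list(rep(0, npar))
  if (!is.null(prev_eta)) {
    pe <- rep(0, npar)
    pe[seq_along(prev_eta)] <- prev_eta
    cand[[length(cand) + 1]] <- pmin(pmax(pe, -bounds), bounds)
  }
  n_rand <- max(0L, n_starts - length(cand))
  if (n_rand > 0) {
    Om <- iiv_cov(params)
    r_iiv <- MASS::mvrnorm(n_rand, rep(0, 6), Om)
    if (n_rand == 1) r_iiv <- matrix(r_iiv, nrow = 1)
    r <- cbind(r_iiv, if (n_occ > 0) {
      matrix(rnorm(n_rand * 4 * n_occ, 0, rep(rep(params$iov_sd, each = n_rand), n_occ)),
             nrow = n_rand)
    })
    r <- pmin(pmax(r, matrix(-bounds, n_rand, npar, byrow = TRUE)),
              matrix(bounds, n_rand, npar, byrow = TRUE))
    for (i in seq_len(nrow(r))) cand[[length(cand) + 1]] <- r[i, ]
  }
  cand_obj <- vapply(cand, fn, numeric(1))

  ## always optimise from zeros; add the best-scoring other candidates
  ord <- order(cand_obj)
  starts <- unique(c(1L, ord))[seq_len(min(n_optimize, length(cand)))]
  fits <- lapply(starts, function(i) {
    tryCatch(
      optim(cand[[i]], fn, gr = function(x) fd_gradient(fn, x),
            method = "L-BFGS-B", lower = -bounds, upper = bounds,
            control = list(maxit = maxit, factr = 1e-6 / .Machine$double.eps)),
      error = function(e) NULL
    )
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop("EBE estimation failed from every start; candidate objectives: ",
         paste(signif(cand_obj[starts], 6), collapse = ", "), call. = FALSE)
  }
  fits <- fits[ok]
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  eta <- best$par
  eta_iov <- NULL
  if (n_occ > 0) {
    eta_iov <- matrix(eta[-(1:6)], nrow = n_occ, byrow = TRUE,
                      dimnames = list(as.character(occasion_days), IOV_NAMES))
  }
  structure(list(
    eta_iiv = setNames(eta[1:6], IIV_NAMES),
    eta_iov = eta_iov,
    eta = eta,
    objective = best$value,
    convergence = best$convergence,
    n_starts = length(cand),
    candidate_objectives = cand_obj,
    occasion_days = if (n_occ > 0) occasion_days else integer(0),
    n_obs = sum(data$EVID == 0L),
    variant = params$variant
  ), class = "ebe_fit")
}

#' @export
print.ebe_fit <- function(x, ...) {
  cat("<ebe_fit> MAP random-effect estimates (", x$n_obs, " observations, ",
      x$n_starts, " starts)\n", sep = "")
  cat("  -2 log posterior:", format(x$objective, digits = 6),
      if (x$convergence == 0) "(converged)" else "(NOT converged)", "\n")
  cat("  IIV etas:", paste(names(x$eta_iiv), signif(x$eta_iiv, 3),
                           sep = "=", collapse = " "), "\n")
  if (!is.null(x$eta_iov)) {
    for (d in rownames(x$eta_iov)) {
      cat("  occasion day ", d, ": ",
          paste(colnames(x$eta_iov), signif(x$eta_iov[d, ], 3),
                sep = "=", collapse = " "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Tidy an EBE fit
#'
#' @param x an `ebe_fit` object.
#' @param ... unused.
#' @return `tidy()`: a tibble with one row per random effect (`term`,
#'   `level`, `estimate`); `glance()`: a one-row tibble with `objective`,
#'   `convergence`, `n_starts`, `n_obs`.
#' @export
tidy.ebe_fit <- function(x, ...) {
  out <- tibble::tibble(term = paste0("iiv_", names(x$eta_iiv)),
                        level = "subject",
                        estimate = unname(x$eta_iiv))
  if (!is.null(x$eta_iov)) {
    iov <- tidyr::expand_grid(day = rownames(x$eta_iov),
                              param = colnames(x$eta_iov))
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = paste0("iov_", iov$param),
      level = paste0("day_", iov$day),
      estimate = as.vector(t(x$eta_iov))
    ))
  }
  out
}

#' @rdname tidy.ebe_fit
#' @export
glance.ebe_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, convergence = x$convergence,
                 n_starts = x$n_starts, n_obs = x$n_obs)
}
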