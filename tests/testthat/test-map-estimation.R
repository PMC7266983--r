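p <- rif_params()

make_dataset <- function(subj, eta_iiv, iov, days = c(1, 7), seed = 1,
                         sigma = p$sigma_log, dose = 1800) {
  simulate_observations(p, subj, daily_regimen(dose, max(days)),
                        sampling_schedule(days = days), eta_iiv, iov,
                        sigma_log = sigma, seed = seed)
}

test_that("MAP objective matches an independent density computation", {
  set.seed(21)
  et <- draw_etas(p, 1, c(1, 7), seed = 22)
  iov <- rifmipd:::iov_slice(et$iov, 1)
  ds <- make_dataset(typ(), et$iiv[1, ], iov, seed = 23)
  for (eta in list(rep(0, 14), c(rnorm(6, 0, 0.2), rnorm(8, 0, 0.1)))) {
    got <- map_objective(eta, ds, p, occasion_days = c(1, 7))
    ## oracle: predictions from the public profile simulator plus direct
    ## normal/censored density evaluation
    e_iiv <- setNames(eta[1:6], rifmipd:::IIV_NAMES)
    e_iov <- matrix(eta[-(1:6)], 2, 4, byrow = TRUE,
                    dimnames = list(c("1", "7"), rifmipd:::IOV_NAMES))
    obs <- ds[ds$EVID == 0L, ]
    pred <- simulate_profile(p, typ(), daily_regimen(1800, 7), obs$TIME,
                             e_iiv, e_iov, rtol = 1e-5, atol = 1e-7)$conc
    sig <- p$sigma_log
    q <- obs$BLQ == 0L
    ll <- -2 * sum(dnorm(log(obs$DV[q]), log(pred[q]), sig, log = TRUE))
    zb <- ifelse(pred[!q] > 1e-12,
                 (log(obs$DV[!q]) - log(pmax(pred[!q], 1e-300))) / sig, Inf)
    ll <- ll - 2 * sum(pnorm(zb, log.p = TRUE))
    Om <- iiv_cov(p)
    ll <- ll + drop(eta[1:6] %*% solve(Om) %*% eta[1:6]) +
      determinant(Om)$modulus[1] + 6 * log(2 * pi)
    ll <- ll + sum(sweep(e_iov^2, 2, p$iov_sd^2, "/")) +
      2 * sum(log(2 * pi * p$iov_sd^2))
    expect_equal(got, ll, tolerance = 1e-6)
  }
})

test_that("fully censored data with negligible predictions cost nothing", {
  ## all records BLQ and predictions far below the LLOQ: each M3 term is
  ## log(1) = 0, leaving only the prior
  ds <- make_dataset(typ(), rifmipd:::zero_iiv(), NULL, days = 1, sigma = 0,
                     dose = 600)
  ds$DV[ds$EVID == 0L] <- 1e4 # LLOQ recorded on BLQ rows
  ds$BLQ[ds$EVID == 0L] <- 1L
  got <- map_objective(rep(0, 10), ds, p, occasion_days = 1)
  Om <- iiv_cov(p)
  prior0 <- determinant(Om)$modulus[1] + 6 * log(2 * pi) +
    sum(log(2 * pi * p$iov_sd^2))
  expect_equal(got, prior0, tolerance = 1e-6)
})

test_that("noise-free data at the generating etas sit at a near-zero mode", {
  ds <- make_dataset(typ(), rifmipd:::zero_iiv(), NULL, days = 1, sigma = 0)
  f0 <- map_objective(rep(0, 10), ds, p, occasion_days = 1)
  ## residuals vanish at zero etas, so any perturbation increases the
  ## objective
  for (i in c(1, 2, 5)) {
    eta <- rep(0, 10)
    eta[i] <- 0.3
    expect_gt(map_objective(eta, ds, p, occasion_days = 1), f0)
  }
})

test_that("rich noise-free sampling recovers the identifiable etas", {
  ## the no-noise limit taken consistently: data simulated without residual
  ## error, a near-zero residual SD in the estimation model, and sampling
  ## dense enough (15-min grid over absorption) to resolve the input pulse.
  ## The transit-compartment number NN has an essentially flat likelihood
  ## even under this design (its eta is prior-dominated by construction),
  ## so exact recovery is asserted for the five identifiable etas.
  p_rich <- rif_params("with_iov", sigma_log = 0.05, iov_sd = c(0, 0, 0, 0))
  eta_true <- setNames(c(0.25, -0.2, 0.05, 0.3, -0.25, 0.4),
                       rifmipd:::IIV_NAMES)
  ds <- simulate_observations(p_rich, typ(), daily_regimen(1800, 2),
                              sampling_schedule(days = c(1, 2),
                                                offsets = c(seq(0.25, 4, 0.25),
                                                            5, 6, 8, 10, 12,
                                                            16, 20, 23)),
                              eta_true, NULL, sigma_log = 0, seed = 25)
  fit <- estimate_ebes(ds, p_rich, occasion_days = c(1, 2), seed = 26)
  expect_equal(fit$convergence, 0)
  idf <- c("vmax", "km", "v", "ka", "mtt")
  expect_lt(max(abs(fit$eta_iiv[idf] - eta_true[idf])), 0.05)
  ## the flat NN direction falls back toward the prior mode, and the
  ## objective at the fit is at least as low as at the generating etas
  expect_lt(abs(fit$eta_iiv[["nn"]]), abs(eta_true[["nn"]]))
  f <- rifmipd:::make_map_objective(ds, p_rich, occasion_days = c(1, 2))
  expect_lte(fit$objective, f(unname(eta_true)) + 1e-6)
})

test_that("estimation requires observations and improves with more starts", {
  ds <- make_dataset(typ(), rifmipd:::zero_iiv(), NULL, days = 1, seed = 30)
  empty <- ds[ds$EVID == 1L, ]
  expect_error(estimate_ebes(empty, p), "observation")
  f1 <- estimate_ebes(ds, p, occasion_days = 1, n_starts = 1, seed = 31)
  f100 <- estimate_ebes(ds, p, occasion_days = 1, n_starts = 100, seed = 31)
  expect_lte(f100$objective, f1$objective + 1e-8)
  ## the returned minimum never exceeds any tried initialisation
  expect_true(all(f100$objective <= f100$candidate_objectives + 1e-8))
  ## deterministic under a seed
  f100b <- estimate_ebes(ds, p, occasion_days = 1, n_starts = 100, seed = 31)
  expect_identical(f100$eta, f100b$eta)
})

test_that("sparse-data EBEs shrink toward zero", {
  set.seed(32)
  n <- 100
  covs <- sample_covariates(n, seed = 33)
  etas <- draw_etas(p, n, 1, seed = 34)
  ratio <- vapply(seq_len(n), function(i) {
    ds <- simulate_observations(p, covs[i, ], daily_regimen(1800, 1),
                                sampling_schedule(days = 1),
                                etas$iiv[i, ], rifmipd:::iov_slice(etas$iov, i),
                                seed = 35 + i)
    fit <- estimate_ebes(ds, p, occasion_days = 1, seed = 36 + i)
    mean(abs(fit$eta_iiv)) / mean(abs(etas$iiv[i, ]))
  }, numeric(1))
  expect_lt(mean(ratio), 1)
})

test_that("tidy and glance summarise an EBE fit", {
  ds <- make_dataset(typ(), rifmipd:::zero_iiv(), NULL, days = 1, seed = 40)
  fit <- estimate_ebes(ds, p, occasion_days = 1, seed = 41)
  td <- tidy(fit)
  expect_equal(nrow(td), 10)
  expect_named(td, c("term", "level", "estimate"))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 3)
  expect_equal(gl$objective, fit$objective)
})
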