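p <- rif_params()

test_that("fat-free mass follows the sex-specific power functions", {
  expect_equal(ffm_from_wt(53.9, "male"), 2.541 * 53.9^0.728)
  expect_equal(round(ffm_from_wt(53.9, "male"), 1), 46.3)
  expect_equal(ffm_from_wt(40.2, "female"), 2.496 * 40.2^0.669)
  expect_error(ffm_from_wt(-1, "male"))
})

test_that("covariate sampling reproduces the cohort structure", {
  covs <- sample_covariates(10000, seed = 1)
  expect_lt(abs(mean(covs$sex == "male") - 0.711), 0.015)
  m <- covs[covs$sex == "male", ]
  f <- covs[covs$sex == "female", ]
  expect_true(all(m$wt >= 40.7 & m$wt <= 74.0))
  expect_true(all(f$wt >= 40.2 & f$wt <= 84.2))
  ## analytic truncated-normal means (the generator design); truncation
  ## shifts the female mean ~1.3 kg above the printed location parameter
  tmean <- function(mu, s, a, b) {
    za <- (a - mu) / s; zb <- (b - mu) / s
    mu + s * (dnorm(za) - dnorm(zb)) / (pnorm(zb) - pnorm(za))
  }
  expect_lt(abs(mean(m$wt) - tmean(55.8, 7.4, 40.7, 74.0)), 0.3)
  expect_lt(abs(mean(f$wt) - tmean(53.8, 10.7, 40.2, 84.2)), 0.6)
  expect_lt(abs(mean(m$wt) - 55.8), 1.0)
  expect_lt(abs(mean(f$wt) - 53.8), 2.5)
  expect_equal(covs$ffm, ffm_from_wt(covs$wt, covs$sex))
  expect_true(all(covs$ffm < covs$wt))
  expect_identical(sample_covariates(50, seed = 7),
                   sample_covariates(50, seed = 7))
  expect_error(sample_covariates(0), ">= 1")
})

test_that("random-effect draws match the declared covariance", {
  et <- draw_etas(p, 10000, c(1, 7), seed = 3)
  expect_lt(abs(sd(et$iiv[, "vmax"]) / 0.300 - 1), 0.03)
  expect_lt(abs(cor(et$iiv[, "vmax"], et$iiv[, "km"]) - 0.389), 0.05)
  expect_lt(abs(sd(et$iov[, "1", "mtt"]) / 0.564 - 1), 0.05)
  ## no-IOV variant yields exactly zero occasion etas
  e0 <- draw_etas(rif_params("no_iov"), 100, c(1, 7), seed = 4)
  expect_true(all(e0$iov == 0))
  expect_identical(draw_etas(p, 20, 1, seed = 5), draw_etas(p, 20, 1, seed = 5))
})

test_that("observation simulation applies log-additive error and censoring", {
  reg <- daily_regimen(1800, 7)
  sch <- sampling_schedule(days = c(1, 7))
  ## noise-free observations equal the model predictions exactly
  ds0 <- simulate_observations(p, typ(), reg, sch, sigma_log = 0, seed = 1)
  obs0 <- ds0[ds0$EVID == 0L & ds0$BLQ == 0L, ]
  pred <- simulate_profile(p, typ(), reg, obs0$TIME)$conc
  expect_equal(obs0$DV, pred, tolerance = 1e-10)
  ## BLQ records carry the LLOQ value, and everything below lloq is flagged
  ds0_blq <- ds0[ds0$EVID == 0L & ds0$BLQ == 1L, ]
  expect_true(all(ds0_blq$DV == 0.3))
  pred_blq <- simulate_profile(p, typ(), reg, ds0_blq$TIME)$conc
  expect_true(all(pred_blq < 0.3))
  ## an absurdly high LLOQ censors every record
  ds_hi <- simulate_observations(p, typ(), reg, sch, lloq = 1000, seed = 1)
  expect_true(all(ds_hi$BLQ[ds_hi$EVID == 0L] == 1L))
  ## residual-error calibration: log-residual SD near sigma_log
  set.seed(1)
  many <- replicate(2000, {
    d <- simulate_observations(p, typ(), daily_regimen(1800, 1),
                               sampling_schedule(days = 1),
                               sigma_log = 0.236, seed = NULL)
    d$DV[d$EVID == 0L & d$BLQ == 0L]
  }, simplify = FALSE)
  resid <- log(unlist(many)) -
    log(rep(simulate_profile(p, typ(), daily_regimen(1800, 1),
                             c(2, 4))$conc, times = 2000))
  expect_lt(abs(sd(resid) / 0.236 - 1), 0.05)
})

test_that("dose and observation records are ordered and labelled", {
  ds <- simulate_observations(p, typ(), daily_regimen(1800, 7),
                              sampling_schedule(days = c(1, 7)), seed = 2)
  expect_true(!is.unsorted(ds$TIME))
  ## the dose at a sampling day precedes its post-dose samples
  i_dose <- which(ds$TIME == 144 & ds$EVID == 1L)
  i_obs <- which(ds$TIME == 146)
  expect_lt(i_dose, i_obs)
  expect_equal(unique(ds$OCC[ds$EVID == 0L]), c(1L, 2L))
  ## every observation maps to exactly one occasion
  expect_true(all(!is.na(ds$OCC[ds$EVID == 0L])))
})

test_that("weight-based starting doses land on the tablet grid", {
  expect_equal(assign_initial_dose(53.9, 35), 1800) # 1886.5 rounds down
  expect_equal(assign_initial_dose(54.9, 35), 1800) # 1921.5 rounds down
  expect_equal(assign_initial_dose(60, 10), 600)    # exact multiple
  ## exact mid-point ties round to the lower dose
  expect_equal(assign_initial_dose(1950 / 35, 35), 1800)
  ## floor at the minimum dose
  expect_equal(assign_initial_dose(30, 10), 600)
  expect_true(all(assign_initial_dose(runif(50, 40, 85), 35) %% 300 == 0))
})

test_that("NONMEM-style datasets round-trip through CSV", {
  ds <- simulate_observations(p, typ(), daily_regimen(1800, 7),
                              sampling_schedule(days = c(1, 7)), seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_nm_dataset(ds, f)
  ## header row and "." for missing values
  lines <- readLines(f)
  expect_match(lines[1], "^ID,TIME,AMT,DV")
  expect_match(lines[2], "\\.")
  back <- read_nm_dataset(f)
  expect_equal(as.data.frame(back), as.data.frame(ds), tolerance = 1e-9)
})
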