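p <- rif_params()

test_that("bioavailability follows the saturable dose dependence", {
  ## at the 450-mg reference and at 450 + ED50 (half-maximal increase)
  expect_equal(bioavailability(450, p), 1)
  expect_equal(bioavailability(450 + p$ed50, p), 1 + p$fmax / 2)
  ## direct evaluation at the 35 mg/kg reference dose
  expect_equal(bioavailability(1800, p),
               1 + 0.504 * 1350 / (67 + 1350), tolerance = 1e-12)
  expect_equal(round(bioavailability(1800, p), 3), 1.480)
  doses <- seq(0, 3300, by = 50)
  expect_true(all(diff(bioavailability(doses, p)) >= 0))
  expect_equal(bioavailability(1800, p, eta_f = 0.2),
               bioavailability(1800, p) * exp(0.2))
  expect_error(bioavailability(-10, p), "non-negative")
})

test_that("Michaelis-Menten clearance saturates and decreases in Cp", {
  expect_equal(mm_clearance(0, 525, 35.3), 525 / 35.3)
  expect_equal(mm_clearance(35.3, 525, 35.3), 525 / (2 * 35.3))
  cp <- seq(0, 80, by = 5)
  expect_true(all(diff(mm_clearance(cp, 525, 35.3)) < 0))
  ## elimination rate CL * Cp approaches Vmax in the saturation limit
  expect_equal(mm_clearance(1e7, 525, 35.3) * 1e7, 525, tolerance = 1e-5)
  expect_error(mm_clearance(-1, 525, 35.3), "non-negative")
})

test_that("transit input is a normalised gamma pulse", {
  expect_equal(transit_input_rate(0, 1800, 1.48, 0.51, 23.8), 0)
  ## adaptive-quadrature oracle: total absorbed mass equals F * dose
  total <- integrate(function(t) transit_input_rate(t, 1800, 1.48, 0.51, 23.8),
                     0, Inf, rel.tol = 1e-9)$value
  expect_equal(total, 1.48 * 1800, tolerance = 1e-3)
  expect_equal(total, 2664, tolerance = 1e-3)
  expect_error(transit_input_rate(-1, 100, 1, 0.5, 5), "non-negative")
})

test_that("structural derivatives vanish at the drug-free equilibrium", {
  y <- c(depot = 0, central = 0, enz = 1, cum_auc = 0, cum_elim = 0)
  d <- pk_rhs(y, t = 10, p, typ())
  expect_equal(unname(d), rep(0, 5))
})

test_that("enzyme pool equilibrates at 1 + Emax under saturating drug", {
  ip <- rifmipd:::individual_params(p, 44.6)
  cp_big <- 1e4
  y <- c(depot = 0, central = ip$v * cp_big, enz = 1 + p$emax_enz,
         cum_auc = 0, cum_elim = 0)
  d <- pk_rhs(y, t = 1, p, typ())
  expect_equal(d[["enz"]], 0, tolerance = 1e-5)
  expect_equal(1 + p$emax_enz, 2.16)
})

test_that("single-dose mass balance closes to 0.1%", {
  pr <- simulate_profile(p, typ(), daily_regimen(1800, 1), times = 240)
  f_dose <- bioavailability(1800, p) * 1800
  expect_equal(unname(pr$depot + pr$central + pr$cum_elim), f_dose,
               tolerance = 1e-3)
  ## essentially everything eliminated by 240 h
  expect_lt(pr$central, 1e-3 * f_dose)
})

test_that("compiled integrator matches an independent lsoda solution", {
  skip_if_not_installed("deSolve")
  set.seed(11)
  eta <- setNames(rnorm(6, 0, 0.2), rifmipd:::IIV_NAMES)
  iov <- matrix(rnorm(8, 0, 0.3), 2, 4,
                dimnames = list(c("1", "3"), rifmipd:::IOV_NAMES))
  reg <- daily_regimen(1800, 3)
  times <- c(1, 2, 5, 23.9, 26, 49, 60, 71.9)
  mine <- simulate_profile(p, typ(), reg, times, eta, iov)
  ref <- desolve_profile(p, typ(), reg, times, eta, iov)
  ip <- rifmipd:::individual_params(p, 44.6, eta)
  expect_equal(mine$conc, ref[, "central"] / ip$v, tolerance = 1e-5)
  expect_equal(mine$cum_auc, ref[, "cum_auc"], tolerance = 1e-5)
  expect_equal(mine$enz, ref[, "enz"], tolerance = 1e-6)
})

test_that("profiles are deterministic and tolerance-converged", {
  a <- simulate_profile(p, typ(), daily_regimen(1800, 2), c(2, 26, 47))
  b <- simulate_profile(p, typ(), daily_regimen(1800, 2), c(2, 26, 47))
  expect_identical(a, b)
  auc1 <- auc_0_24(p, typ(), 1800, 14)
  auc2 <- auc_0_24(p, typ(), 1800, 14, rtol = 5e-9, atol = 5e-11)
  expect_equal(auc1, auc2, tolerance = 1e-3)
  ## zero dose gives an identically drug-free system
  z <- simulate_profile(p, typ(), daily_regimen(0, 3), c(0, 10, 50))
  expect_true(all(z$conc == 0) && all(z$enz == 1))
  expect_equal(auc_0_24(p, typ(), 0, 5), 0)
})

test_that("daily AUC declines with auto-induction and tracks the targets", {
  aucs <- auc_0_24(p, typ(), 1800, c(1, 7, 14, 24, 25, 30))
  expect_true(all(diff(aucs) < 0))
  tt <- target_table()
  expect_gt(aucs[1], tt$lower[tt$day == 1])
  expect_lt(aucs[1], tt$upper[tt$day == 1])
  expect_gt(aucs[3], tt$lower[tt$day == 14])
  expect_lt(aucs[3], tt$upper[tt$day == 14])
  ## steady state beyond day 24: < 1% change from day 25 to day 30
  expect_lt(abs(aucs[6] / aucs[5] - 1), 0.01)
})

test_that("AUC is strictly increasing and superlinear in dose", {
  doses <- dose_grid()
  aucs <- vapply(doses, function(d) auc_0_24(p, typ(), d, 14), numeric(1))
  expect_true(all(diff(aucs) > 0))
  ## dose-normalised AUC grows with dose (Emax bioavailability + saturable
  ## elimination)
  expect_true(all(diff(aucs / doses) > 0))
  for (d in c(900, 1200, 1650)) {
    expect_gt(auc_0_24(p, typ(), 2 * d, 14), 2 * auc_0_24(p, typ(), d, 14))
  }
})

test_that("augmented-state AUC agrees with dense trapezoid quadrature", {
  tt <- seq(24 * 13, 24 * 14, by = 0.05)
  pr <- simulate_profile(p, typ(), daily_regimen(1800, 14), tt)
  trap <- sum(diff(tt) * (head(pr$conc, -1) + tail(pr$conc, -1)) / 2)
  expect_equal(auc_0_24(p, typ(), 1800, 14), trap, tolerance = 5e-3)
})
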