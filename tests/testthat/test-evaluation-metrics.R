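test_that("variability magnitude is the population SD of log values", {
  expect_equal(variability_magnitude(rep(42, 10)), 0)
  ## hand computation: ln-deviations (0.5, 0, -0.5), divisor N = 3
  x <- c(100 * exp(0.5), 100, 100 * exp(-0.5))
  expect_equal(variability_magnitude(x), 100 * sqrt(1 / 6))
  expect_equal(round(variability_magnitude(x), 2), 40.82)
  ## scale invariance
  set.seed(2)
  y <- rlnorm(200, 5, 0.4)
  expect_equal(variability_magnitude(y), variability_magnitude(1000 * y))
  ## Monte-Carlo consistency with the generating sigma
  set.seed(3)
  z <- rlnorm(10000, meanlog = 5, sdlog = 0.258)
  expect_lt(abs(variability_magnitude(z) - 25.8), 0.6)
  expect_error(variability_magnitude(c(1, -1, 2)), "positive")
  expect_error(variability_magnitude(3), "at least two")
})

test_that("prediction intervals follow the (N+1)-rank order statistic", {
  ## (N+1) * 0.025 = 1 exactly: the interval is the sample min and max
  expect_equal(prediction_interval(1:39, 0.95),
               c(lower = 1, upper = 39))
  ## fractional ranks 25.025 and 975.975, linearly interpolated
  expect_equal(prediction_interval(1:1000, 0.95),
               c(lower = 25.025, upper = 975.975))
  ## hand-rolled rank oracle on random data, several levels
  set.seed(4)
  x <- rlnorm(500, 3, 0.7)
  for (lev in c(0.5, 0.75, 0.9, 0.95)) {
    a <- (1 - lev) / 2
    expect_equal(prediction_interval(x, lev),
                 c(lower = rank_quantile(x, a),
                   upper = rank_quantile(x, 1 - a)))
  }
  ## widening the level widens the interval
  pi50 <- prediction_interval(x, 0.5)
  pi95 <- prediction_interval(x, 0.95)
  expect_lt(pi95[1], pi50[1])
  expect_gt(pi95[2], pi50[2])
  expect_error(prediction_interval(1:10, 0.95), "at least")
})

test_that("individual prediction error is the signed percent deviation", {
  expect_equal(individual_prediction_error(1500, 1800), -100 / 6)
  expect_equal(round(individual_prediction_error(1500, 1800), 2), -16.67)
  expect_equal(individual_prediction_error(1800, 1800), 0)
  expect_equal(individual_prediction_error(2100, 1500), 40)
  expect_error(individual_prediction_error(1500, 0), "positive")
})

test_that("MAPE and rRMSE match loop-based oracles to machine precision", {
  expect_equal(mape(c(1500, 1800), c(1800, 1800)), 100 / 12)
  expect_equal(round(mape(c(1500, 1800), c(1800, 1800)), 2), 8.33)
  expect_equal(round(rrmse(c(1500, 1800), c(1800, 1800)), 2), 11.79)
  expect_equal(mape(900, 600), 50)
  expect_equal(rrmse(900, 600), 50)
  expect_equal(mape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(5)
  pred <- sample(dose_grid(), 100, replace = TRUE)
  true <- sample(dose_grid(), 100, replace = TRUE)
  m <- r <- 0
  for (i in 1:100) {
    m <- m + abs(pred[i] - true[i]) / true[i]
    r <- r + (pred[i] - true[i])^2 / true[i]^2
  }
  expect_equal(mape(pred, true), 100 * m / 100, tolerance = 1e-14)
  expect_equal(rrmse(pred, true), 100 * sqrt(r / 100), tolerance = 1e-15)
  expect_error(mape(1:3, 1:4), "equal length")
})

test_that("paired bootstrap flags real differences and not null ones", {
  set.seed(6)
  true <- sample(dose_grid(), 80, replace = TRUE)
  noisy <- true * exp(rnorm(80, 0, 0.15))
  same <- paired_difference_ci("mape", noisy, noisy, true, seed = 1)
  expect_equal(same$estimate, 0)
  expect_false(same$significant)
  better <- paired_difference_ci("mape", noisy, true, true, seed = 1)
  expect_true(better$significant)
  expect_lt(better$upper, 0)
  expect_error(paired_difference_ci("mape", noisy[-1], noisy, true), "paired")
})

test_that("bootstrap difference CI attains nominal coverage", {
  ## synthetic metric with a known analytic difference: arm A exact,
  ## arm B multiplicatively biased, MAPE difference = E|e| * 100
  set.seed(7)
  n <- 60
  true_mape <- 100 * sqrt(2 / pi) * 0.2 # E|N(0, 0.2)| folded normal
  hits <- vapply(seq_len(500), function(r) {
    true <- rep(1500, n)
    pred_b <- true * (1 + rnorm(n, 0, 0.2))
    ci <- paired_difference_ci("mape", true, pred_b, true, B = 400)
    ci$lower <= true_mape && true_mape <= ci$upper
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.95), 0.035)
})
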