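test_that("cohens_dz matches hand computation and is antisymmetric", {
  d <- c(-2, -1, 0, -3)
  expect_equal(cohens_dz(d), -1.5 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(cohens_dz(-d), -cohens_dz(d), tolerance = 1e-12)
  expect_error(cohens_dz(c(1, 1, 1)), "zero standard deviation")
  expect_error(cohens_dz(1), "at least 2")
})

test_that("the quadratic effect-size model recovers exact and noisy truths", {
  x <- seq(-3, 0.5, by = 0.25)
  y <- 0.13 * x^2 + 0.95 * x - 0.03
  fit <- fit_effect_model(x, y)
  expect_equal(fit$a, 0.13, tolerance = 1e-9)
  expect_equal(fit$b, 0.95, tolerance = 1e-9)
  expect_equal(fit$c, -0.03, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  expect_error(fit_effect_model(c(-1, 0), c(1, 2)), "3 points")
  expect_error(fit_effect_model(c(1, 1, 1), c(1, 2, 3)), "3 points")

  # noisy recovery within 3 standard errors of the generating coefficients
  set.seed(21)
  xn <- runif(120, -3.5, 0.5)
  yn <- 0.13 * xn^2 + 0.95 * xn - 0.03 + rnorm(120, 0, 0.15)
  fitn <- fit_effect_model(xn, yn)
  lmfit <- summary(lm(yn ~ xn + I(xn^2)))$coefficients
  expect_lt(abs(fitn$c - (-0.03)), 3 * lmfit[1, 2])
  expect_lt(abs(fitn$b - 0.95), 3 * lmfit[2, 2])
  expect_lt(abs(fitn$a - 0.13), 3 * lmfit[3, 2])
})

test_that("predict_dz evaluates the quadratic and its algebraic identity", {
  mod <- effect_size_model(a = 0.13, b = 0.95, c = -0.03, r_squared = 0.86)
  expect_equal(predict_dz(mod, -0.5), 0.13 * 0.25 - 0.475 - 0.03)
  expect_equal(predict_dz(mod, -0.5), -0.4725)
  expect_equal(predict_dz(mod, 0), -0.03)
  for (x in c(-2, -0.5, 1.3)) {
    expect_equal(predict_dz(mod, x) - predict_dz(mod, -x), 2 * 0.95 * x,
                 tolerance = 1e-12)
  }
})

test_that("noncentral-t power behaves at its analytic anchors", {
  expect_equal(power_one_sample_t(0, 24), 0.05, tolerance = 1e-12)
  expect_equal(power_one_sample_t(0, 24, alpha = 0.01, tails = 1), 0.01,
               tolerance = 1e-12)
  # sign of d is irrelevant
  expect_equal(power_one_sample_t(-0.5, 20), power_one_sample_t(0.5, 20))
  # large-n normal approximation: power ~ pnorm(|d| sqrt(n) - z_{1-a/2})
  napprox <- pnorm(0.2 * sqrt(500) - qnorm(0.975))
  expect_equal(power_one_sample_t(0.2, 500), napprox, tolerance = 0.002)
  expect_error(power_one_sample_t(0.5, 1), "at least 2")
})

test_that("power agrees with a Monte-Carlo paired t-test", {
  # one (d, n) cell at high replication; the full grid runs in the
  # acceptance suite
  d <- 0.5
  n <- 24
  reps <- 2e5
  crit <- qt(0.975, n - 1)
  set.seed(17)
  X <- matrix(rnorm(n * reps, mean = d), n, reps)
  mvec <- colMeans(X)
  s2 <- (colSums(X^2) - n * mvec^2) / (n - 1)
  tstat <- mvec / sqrt(s2 / n)
  expect_lt(abs(mean(abs(tstat) > crit) - power_one_sample_t(d, n)), 0.005)
})

test_that("required_n solves the boundary exactly and is monotone", {
  expect_identical(required_n(0.469), 38L)
  expect_identical(required_n(0.4), 52L)
  for (d in c(0.2, 0.4, 0.469, 0.8)) {
    n <- required_n(d)
    expect_gte(power_one_sample_t(d, n), 0.8)
    expect_lt(power_one_sample_t(d, n - 1), 0.8)
  }
  ds <- c(0.2, 0.3, 0.469, 0.7, 1.2)
  ns <- vapply(ds, required_n, integer(1))
  expect_true(all(diff(ns) <= 0))
  expect_error(required_n(0), "unreachable")
})

test_that("binomial critical counts match exhaustive enumeration", {
  expect_identical(binomial_critical_count(24), 18L)
  expect_identical(binomial_critical_count(48), 32L)
  expect_true(is.na(binomial_critical_count(5)))  # 2*P(X>=5) = 0.0625

  # brute force over all k for a spread of n
  for (n in c(1, 7, 24, 48, 133)) {
    brute <- NA_integer_
    for (k in 0:n) {
      p <- 2 * sum(dbinom(k:n, n, 0.5))
      if (p <= 0.05) {
        brute <- k
        break
      }
    }
    expect_identical(binomial_critical_count(n), brute, label = paste(n))
  }

  # the exact (small-p) method can only be at most as strict
  for (n in c(10, 24, 48)) {
    expect_lte(binomial_critical_count(n, method = "exact"),
               binomial_critical_count(n))
  }
})

test_that("power_table composes prediction and sample-size solving", {
  mod <- effect_size_model(a = 0, b = 0, c = -0.469)
  tab <- power_table(c(-1, -0.5, -0.25), mod)
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$required_n == 38L))

  mod2 <- effect_size_model(a = 0.13, b = 0.95, c = -0.03)
  amps <- seq(-2, -0.25, by = 0.25)
  tab2 <- power_table(amps, mod2)
  # |d| increases with more negative amplitude over this range,
  # so required n decreases toward stronger SPNs
  expect_true(all(diff(tab2$required_n) >= 0))
})

test_that("amplitude regression recovers generator coefficients on a noise-free catalogue", {
  cfg <- synth_config(n_experiments = 8, n_range = c(2, 3), noise_sd = 0,
                      between_sd = 0, experiment_sd = 0, seed = 12)
  cat1 <- generate_catalogue(cfg)
  amps <- vapply(cat1$experiments, function(e) {
    window_mean(grand_average(e, "regular"), cluster4, c(300, 1000)) -
      window_mean(grand_average(e, "random"), cluster4, c(300, 1000))
  }, numeric(1))
  w <- vapply(cat1$experiments, function(e) e$w_load, numeric(1))
  task <- vapply(cat1$experiments, function(e) e$task_relevant, numeric(1))
  reg <- amplitude_regression(amps, w, task)
  expect_equal(reg$intercept, 0.071, tolerance = 1e-6)
  expect_equal(reg$coef_w, -1.669, tolerance = 1e-6)
  expect_equal(reg$coef_task, -0.416, tolerance = 1e-6)
  expect_equal(reg$r_squared, 1, tolerance = 1e-6)

  # OLS equivariance: shifting every amplitude moves only the intercept
  reg2 <- amplitude_regression(amps + 2, w, task)
  expect_equal(reg2$intercept, reg$intercept + 2, tolerance = 1e-9)
  expect_equal(reg2$coef_w, reg$coef_w, tolerance = 1e-9)

  expect_error(amplitude_regression(amps, rep(0.5, 8), task),
               "rank-deficient")
  expect_error(amplitude_regression(amps[1:3], w[1:3], task[1:3]),
               "at least 4")
})
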