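# quadratic-trough cut-off and power-model fitting

test_that("an exact quadratic is recovered and its trough defines the cut-off", {
  x <- 1:20
  y <- 60 - 8 * x + 0.5 * x^2
  fit <- fit_quadratic_cutoff(y, t_max = 200)
  expect_equal(unname(fit$coefficients), c(60, -8, 0.5), tolerance = 1e-10)
  expect_equal(fit$vertex, 8.0, tolerance = 1e-10)
  expect_identical(fit$cutoff_trial, 8L)
  expect_false(fit$used_all_trials)
})

test_that("series without an interior trough use all trials", {
  y_lin <- 60 - 2 * (1:20)          # strictly decreasing, c2 ~ 0
  fit <- fit_quadratic_cutoff(y_lin)
  expect_true(fit$used_all_trials)
  expect_identical(fit$cutoff_trial, 20L)

  y_concave <- 30 + 5 * (1:20) - 0.3 * (1:20)^2  # c2 < 0
  fit2 <- fit_quadratic_cutoff(pmax(y_concave, 1), t_max = 200)
  expect_true(fit2$used_all_trials)
})

test_that("the fitted vertex matches a dense-grid argmin of the fitted polynomial", {
  set.seed(11)
  for (rep in 1:20) {
    y <- pmin(60, 55 * (1:20)^-0.4 * exp(rnorm(20, 0, 0.3)))
    fit <- fit_quadratic_cutoff(y)
    cf <- fit$coefficients
    grid <- seq(1, 20, by = 1e-3)
    val <- cf[1] + cf[2] * grid + cf[3] * grid^2
    if (!is.na(fit$vertex) && fit$vertex >= 1 && fit$vertex <= 20)
      expect_equal(fit$vertex, grid[which.min(val)], tolerance = 1.1e-3)
  }
})

test_that("cut-off is invariant under positive affine transforms of latency", {
  set.seed(21)
  y <- pmin(60, 50 * (1:20)^-0.35 * exp(rnorm(20, 0, 0.2)))
  f0 <- fit_quadratic_cutoff(y)
  f1 <- fit_quadratic_cutoff(0.7 * y + 5, t_max = 200)
  expect_equal(f0$vertex, f1$vertex, tolerance = 1e-8)
  expect_identical(f0$cutoff_trial, f1$cutoff_trial)
})

test_that("an exact power law is fitted exactly by both methods", {
  y <- power_series(10, -0.5)
  for (m in c("loglog_ols", "nonlinear_ls")) {
    fit <- fit_power_model(y, 20, method = m)
    expect_equal(fit$a, 10, tolerance = 1e-8)
    expect_equal(fit$b, -0.5, tolerance = 1e-8)
    expect_equal(fit$r_squared, 1, tolerance = 1e-8)
    expect_identical(fit$method, m)
  }
})

test_that("a flat series has zero slope and zero variance explained", {
  fit <- fit_power_model(rep(30, 20), 20)
  expect_identical(fit$b, 0)
  expect_identical(fit$r_squared, 0)
  expect_equal(fit$a, 30, tolerance = 1e-12)
})

test_that("log-log fit equals the closed-form OLS solution from summary sums", {
  set.seed(33)
  for (cutoff in c(5L, 12L, 20L)) {
    y <- pmin(60, 45 * (1:20)^-0.3 * exp(rnorm(20, 0, 0.25)))
    fit <- fit_power_model(y, cutoff)
    # independent closed-form solution from the raw summary sums
    lx <- log(seq_len(cutoff)); ly <- log(y[seq_len(cutoff)])
    k <- cutoff
    b_oracle <- (k * sum(lx * ly) - sum(lx) * sum(ly)) /
      (k * sum(lx^2) - sum(lx)^2)
    a_oracle <- exp((sum(ly) - b_oracle * sum(lx)) / k)
    r2_oracle <- (k * sum(lx * ly) - sum(lx) * sum(ly))^2 /
      ((k * sum(lx^2) - sum(lx)^2) * (k * sum(ly^2) - sum(ly)^2))
    expect_equal(fit$b, b_oracle, tolerance = 1e-10)
    expect_equal(fit$a, a_oracle, tolerance = 1e-10)
    expect_equal(fit$r_squared, r2_oracle, tolerance = 1e-10)
  }
})

test_that("rescaling latencies rescales a and leaves b and R^2 unchanged", {
  set.seed(44)
  y <- pmin(60, 40 * (1:20)^-0.3 * exp(rnorm(20, 0, 0.2)))
  f0 <- fit_power_model(y, 15)
  f1 <- fit_power_model(2.5 * y, 15, t_max = 200)
  expect_equal(f1$b, f0$b, tolerance = 1e-12)
  expect_equal(f1$a, 2.5 * f0$a, tolerance = 1e-10)
  expect_equal(f1$r_squared, f0$r_squared, tolerance = 1e-12)
})

test_that("mean latency to the cut-off is the plain arithmetic mean", {
  expect_identical(mean_latency_to_cutoff(c(10, 20, 30, 40), 4), 25)
  expect_identical(mean_latency_to_cutoff(c(10, 20, 30, 40), 1), 10)
  expect_error(mean_latency_to_cutoff(c(10, 20, 30, 40), 0), "cutoff")
  expect_error(mean_latency_to_cutoff(c(10, 20, 30, 40), 5), "exceeds")
})

test_that("invalid series and cut-offs are rejected", {
  expect_error(fit_quadratic_cutoff(c(10, 20, 30)), "at least 4")
  expect_error(fit_quadratic_cutoff(c(10, -1, 30, 40)), "\\(0, 60\\]")
  expect_error(fit_power_model(power_series(10, -0.3), 3), "cutoff")
  expect_error(fit_power_model(power_series(10, -0.3), 25), "exceeds")
})

test_that("noiseless generator output is identified exactly", {
  y <- simulate_latency_series(50, -0.32, plateau = 20, noise_sd = 0,
                               late_noise_sd = 0, seed = 1)
  res <- derive_learning_rate(y)
  expect_equal(res$b, -0.32, tolerance = 1e-6)
  expect_equal(res$a, 50, tolerance = 1e-4)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
})

test_that("fit quality improves as generator noise shrinks", {
  mean_r2 <- vapply(c(0.4, 0.2, 0.05), function(ns) {
    set.seed(77)
    mean(replicate(40, {
      y <- simulate_latency_series(50, -0.32, plateau = 20, noise_sd = ns,
                                   late_noise_sd = ns)
      derive_learning_rate(y)$r_squared
    }))
  }, numeric(1))
  expect_true(all(diff(mean_r2) > 0))
})
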