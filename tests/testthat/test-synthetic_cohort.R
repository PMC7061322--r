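# synthetic cohort generator: latency series, correlated metrics, arena agent

test_that("a noiseless series is exactly the power curve", {
  y <- simulate_latency_series(10, -0.5, plateau = 20, noise_sd = 0,
                               late_noise_sd = 0)
  expect_equal(y, 10 * (1:20)^-0.5, tolerance = 1e-12)
})

test_that("the latency ceiling binds for a flat curve above it", {
  y <- simulate_latency_series(100, 0, plateau = 20, noise_sd = 0,
                               late_noise_sd = 0, t_max = 60)
  expect_identical(y, rep(60, 20))
})

test_that("log-latency noise has the stated scale", {
  set.seed(5)
  res <- replicate(500, {
    y <- simulate_latency_series(50, -0.32, plateau = 20, noise_sd = 0.2,
                                 late_noise_sd = 0.2, t_max = 500)
    log(y) - log(50 * (1:20)^-0.32)
  })
  expect_equal(sd(res), 0.2, tolerance = 0.05)   # 10,000 replicate trials
})

test_that("invalid latency-series parameters are rejected", {
  expect_error(simulate_latency_series(-1, -0.3, 20), "`a`")
  expect_error(simulate_latency_series(10, -0.3, 20, n_trials = 3),
               "n_trials")
  expect_error(simulate_latency_series(10, -0.3, 20, noise_sd = -0.1),
               "noise_sd")
})

test_that("correlated metrics hit the target correlation with true b", {
  p0 <- cohort_params(10, target_r_fornix_md = 0)
  p44 <- cohort_params(10, target_r_fornix_md = 0.44)
  set.seed(8)
  true_b <- -abs(rnorm(10000, 0.32, 0.08))

  m0 <- induce_correlated_metrics(true_b, p0, seed = 1)
  expect_lt(abs(cor(m0$fornix_md, true_b)), 3 / sqrt(10000))

  m44 <- induce_correlated_metrics(true_b, p44, seed = 1)
  r <- cor(m44$fornix_md, true_b)
  expect_gt(r, 0.41)
  expect_lt(r, 0.47)

  # ILF metrics, volumes and gender are independent of b
  for (cl in c("ilf_md", "ilf_fa", "hippocampal_volume", "etiv", "gender"))
    expect_lt(abs(cor(m44[[cl]], true_b)), 4 / sqrt(10000))
  # FA tracks MD negatively within tract
  expect_lt(cor(m44$fornix_fa, m44$fornix_md), -0.3)

  expect_true(all(m44$fornix_fa > 0 & m44$fornix_fa < 1))
  expect_true(all(m44$ilf_fa > 0 & m44$ilf_fa < 1))
  expect_true(all(m44$fornix_md > 0 & m44$ilf_md > 0))
})

test_that("degenerate metric inputs are rejected", {
  p <- cohort_params(5)
  expect_error(induce_correlated_metrics(c(-0.3, -0.4), p), "length")
  expect_error(induce_correlated_metrics(rep(-0.3, 10), p), "variance")
})

test_that("a fully goal-directed agent beelines to the sensor", {
  traj <- simulate_arena_agent(goal_bias = 1, n_trials = 4, seed = 3)
  expect_true(all(traj$trials$found))
  starts <- rbind(N = c(4, 8), S = c(4, 0), E = c(8, 4), W = c(0, 4))
  d <- sqrt(colSums((t(starts[traj$trials$start, ]) - c(5.6, 5.6))^2))
  speed <- 0.25 / 0.1
  expect_true(all(traj$trials$latency <= ceiling(d / 0.25) * 0.1 + 1e-9))
  expect_true(all(traj$trials$latency >= (d - 0.6) / speed - 1e-9))
})

test_that("trajectories stay inside the arena", {
  traj <- simulate_arena_agent(goal_bias = 0.3, n_trials = 8, seed = 4)
  pts <- as.data.frame(traj)
  expect_true(all(pts$x >= 0 & pts$x <= 8 & pts$y >= 0 & pts$y <= 8))
  # each block of four trials visits all four cardinal starts
  expect_setequal(traj$trials$start[1:4], c("N", "S", "E", "W"))
  expect_setequal(traj$trials$start[5:8], c("N", "S", "E", "W"))
})

test_that("goal bias speeds the agent up on average", {
  t_rand <- simulate_arena_agent(0, n_trials = 500, seed = 6)
  t_goal <- simulate_arena_agent(0.8, n_trials = 500, seed = 6)
  expect_gt(mean(t_rand$trials$latency), mean(t_goal$trials$latency))
})

test_that("out-of-range goal bias is rejected", {
  expect_error(simulate_arena_agent(1.2), "goal_bias")
  expect_error(simulate_arena_agent(-0.1), "goal_bias")
})

test_that("cohorts are reproducible and stable under growth", {
  p <- cohort_params(12, seed = 99)
  c1 <- simulate_cohort(p)
  c2 <- simulate_cohort(p)
  expect_identical(c1, c2)

  bigger <- simulate_cohort(cohort_params(15, seed = 99))
  expect_identical(c1$latencies, bigger$latencies[1:12, ])
  expect_identical(c1$truth, bigger$truth[1:12, ])
})

test_that("a noiseless cohort is identified exactly downstream", {
  p <- cohort_params(30, noise_sd = 0, late_noise_sd = 0,
                     plateau_range = c(20, 20), nonlearner_fraction = 0,
                     seed = 7)
  ch <- simulate_cohort(p)
  m <- as.matrix(ch$latencies[, -1])
  for (i in seq_len(30)) {
    fit <- derive_learning_rate(m[i, ])
    expect_equal(fit$b, ch$truth$true_b[i], tolerance = 1e-6)
  }
})

test_that("cohort outputs respect their range invariants", {
  ch <- simulate_cohort(cohort_params(80, seed = 13))
  lat <- as.matrix(ch$latencies[, -1])
  expect_true(all(lat > 0 & lat <= 60))
  expect_true(all(ch$metrics$fornix_fa > 0 & ch$metrics$fornix_fa < 1))
  expect_true(all(ch$metrics$fornix_md > 0))
  expect_true(all(ch$truth$true_b < 0))
  expect_true(all(ch$metrics$gender %in% c(0, 1)))
  expect_true(all(ch$truth$true_plateau >= 7 & ch$truth$true_plateau <= 20))
})
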