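# directional correlation suite: frequentist tests, Steiger Z, Bayes
# factors, partial correlations, bootstrap comparison

test_that("directional Pearson matches the closed-form t tail and cor.test", {
  set.seed(1)
  x <- rnorm(30); y <- 0.4 * x + rnorm(30)
  res <- pearson_directional(x, y, "greater", bayes = FALSE)
  expect_equal(res$estimate, cor(x, y), tolerance = 1e-14)
  # independent oracle: closed-form t transform
  t_stat <- res$estimate * sqrt(28 / (1 - res$estimate^2))
  expect_equal(res$p, pt(t_stat, 28, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$p,
               cor.test(x, y, alternative = "greater")$p.value,
               tolerance = 1e-12)
  # tail complementarity
  p_less <- pearson_directional(x, y, "less", bayes = FALSE)$p
  expect_equal(res$p + p_less, 1, tolerance = 1e-12)
})

test_that("identical and constant inputs are handled as specified", {
  x <- rnorm(10)
  expect_equal(pearson_directional(x, x, bayes = FALSE)$estimate, 1)
  expect_error(pearson_directional(x, rep(1, 10)), "constant")
  expect_error(pearson_directional(x, rnorm(9)), "equal length")
})

test_that("Spearman uses mid-ranks and is robust to a single outlier", {
  x <- rnorm(20)
  expect_equal(spearman_directional(x, exp(x), bayes = FALSE)$estimate, 1)
  # hand-computed mid-rank case: ranks (1.5,1.5,3.5,3.5) vs (1.5,3.5,1.5,3.5)
  expect_equal(spearman_directional(c(1, 1, 2, 2), c(1, 2, 1, 2),
                                    bayes = FALSE)$estimate, 0)

  set.seed(2)
  x0 <- rnorm(40); y0 <- 0.5 * x0 + rnorm(40, 0, sqrt(0.75))
  x1 <- c(x0, 30); y1 <- c(y0, -30)
  d_rho <- abs(spearman_directional(x1, y1, bayes = FALSE)$estimate -
                 spearman_directional(x0, y0, bayes = FALSE)$estimate)
  d_r <- abs(pearson_directional(x1, y1, bayes = FALSE)$estimate -
               pearson_directional(x0, y0, bayes = FALSE)$estimate)
  expect_lt(d_rho, 0.1)
  expect_gt(d_r, 0.2)
  expect_equal(spearman_directional(x0, y0, bayes = FALSE)$estimate,
               unname(cor(x0, y0, method = "spearman")), tolerance = 1e-12)
})

test_that("Steiger Z agrees with an independent step-by-step evaluation", {
  # spelled-out evaluation of the pooled-correlation formula, kept free of
  # any package code
  steiger_oracle <- function(rjk, rjh, rkh, n) {
    zjk <- 0.5 * log((1 + rjk) / (1 - rjk))
    zjh <- 0.5 * log((1 + rjh) / (1 - rjh))
    rb <- (rjk + rjh) / 2
    num <- rkh * (1 - rb^2 - rb^2) - 0.5 * rb^2 *
      (1 - rb^2 - rb^2 - rkh^2)
    cv <- num / ((1 - rb^2) * (1 - rb^2))
    (zjk - zjh) * sqrt(n - 3) / sqrt(2 - 2 * cv)
  }
  set.seed(3)
  for (i in 1:100) {
    r <- runif(3, -0.8, 0.8)
    n <- sample(10:200, 1)
    st <- steiger_z_dependent(r[1], r[2], r[3], n)
    expect_equal(st$z, steiger_oracle(r[1], r[2], r[3], n),
                 tolerance = 1e-10)
  }
})

test_that("Steiger Z is antisymmetric and null at equality", {
  st0 <- steiger_z_dependent(0.4, 0.4, 0.2, 50)
  expect_identical(st0$z, 0)
  expect_equal(st0$p, 0.5)

  a <- steiger_z_dependent(0.5, 0.3, 0.2, 50)
  b <- steiger_z_dependent(0.3, 0.5, 0.2, 50)
  expect_equal(a$z, -b$z, tolerance = 1e-14)
  expect_error(steiger_z_dependent(1, 0.3, 0.2, 50), "r_jk")
  expect_error(steiger_z_dependent(0.5, 0.3, 0.2, 4), "n")
})

test_that("Bayes factor obeys the symmetric-prior identities", {
  for (r in c(-0.6, -0.3, 0, 0.3, 0.6)) {
    for (n in c(10, 27, 100)) {
      bf <- default_bf_correlation(r, n, "two_sided")
      expect_equal(bf$bf_10, (bf$bf_plus0 + bf$bf_minus0) / 2,
                   tolerance = 1e-6)
    }
  }
  bf0 <- default_bf_correlation(0, 27, "greater")
  expect_equal(bf0$bf_plus0, bf0$bf_minus0, tolerance = 1e-10)
})

test_that("posterior is normalised, with well-defined credible intervals", {
  bf <- default_bf_correlation(0.3, 27, "greater")
  post <- bf$posterior
  total <- integrate(post$density, -1, 1, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-6)

  ci <- posterior_credible_interval(post)
  cdf <- function(q) integrate(post$density, -1, q, rel.tol = 1e-10)$value
  expect_equal(cdf(ci[1]), 0.025, tolerance = 1e-6)
  expect_equal(cdf(ci[2]), 0.975, tolerance = 1e-6)

  # a symmetric posterior yields a symmetric interval
  ci0 <- posterior_credible_interval(default_bf_correlation(0, 27)$posterior)
  expect_equal(ci0[1], -ci0[2], tolerance = 1e-6)

  # intervals widen as n falls at fixed r
  widths <- vapply(c(100, 27, 10), function(n) {
    diff(posterior_credible_interval(
      default_bf_correlation(0.3, n)$posterior))
  }, numeric(1))
  expect_true(all(diff(widths) > 0))

  # unnormalised densities are rejected
  expect_error(posterior_credible_interval(function(rho)
    1.1 * post$density(rho)), "not normalised")
})

test_that("one-sided truncated posterior intervals stay in their half-line", {
  bf <- default_bf_correlation(0.44, 27, "greater")
  ci <- posterior_credible_interval(bf$posterior, side = "positive")
  expect_gt(ci[1], 0)
  expect_lt(ci[2], 1)
})

test_that("partial correlation matches the closed form for one covariate", {
  set.seed(4)
  for (i in 1:20) {
    z <- rnorm(40)
    x <- 0.5 * z + rnorm(40)
    y <- -0.3 * z + 0.4 * x + rnorm(40)
    pc <- partial_correlation(x, y, z, bayes = FALSE)
    rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
    oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(pc$estimate, oracle, tolerance = 1e-10)
  }
})

test_that("orthogonal covariates leave the zero-order correlation unchanged", {
  set.seed(5)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  z0 <- rnorm(40)
  z <- residuals(lm(z0 ~ x + y))   # exactly orthogonal in-sample
  pc <- partial_correlation(x, y, z, bayes = FALSE)
  expect_equal(pc$estimate, cor(x, y), tolerance = 1e-10)
  expect_error(partial_correlation(x, y, cbind(z, z)), "rank deficient")
})

test_that("JZS partial-correlation Bayes factor behaves sensibly", {
  set.seed(6)
  z <- matrix(rnorm(600), ncol = 2)
  x <- 0.6 * z[, 1] + rnorm(300)
  y <- -0.5 * z[, 1] + 0.4 * z[, 2] + rnorm(300)  # x independent of y | z
  bf_null <- jzs_bf_partial_correlation(x, y, z, "two_sided")
  expect_lt(bf_null$bf, 1)

  # zero covariates: same integral with an empty nuisance set, checked
  # against a direct evaluation of the Zellner-Siow marginal in test code
  set.seed(7)
  x2 <- rnorm(40); y2 <- 0.5 * x2 + rnorm(40)
  bf0 <- jzs_bf_partial_correlation(x2, y2, NULL, "two_sided")
  r2 <- summary(lm(y2 ~ x2))$r.squared
  n <- 40
  oracle <- integrate(function(g)
    (1 + g)^((n - 2) / 2) * (1 + g * (1 - r2))^(-(n - 1) / 2) *
      sqrt(n / 2) / gamma(0.5) * g^(-1.5) * exp(-n / (2 * g)),
    0, Inf, rel.tol = 1e-10)$value
  expect_equal(bf0$bf_10, oracle, tolerance = 1e-6)

  # scale invariance of the standardised effect
  bf_scaled <- jzs_bf_partial_correlation(3.7 * x2, y2, NULL, "two_sided")
  expect_equal(bf_scaled$bf, bf0$bf, tolerance = 1e-8)
})

test_that("bootstrap comparison of dependent correlations is calibrated", {
  set.seed(8)
  y <- rnorm(20); x1 <- y + rnorm(20)
  same <- bootstrap_compare_dependent_correlations(y, x1, x1, n_boot = 200,
                                                   seed = 1)
  expect_identical(same$observed, 0)
  expect_identical(c(same$ci_low, same$ci_high), c(0, 0))
  expect_false(same$significant)

  # power on a constructed population: corr(y, x1) = .6, corr(y, x2) = 0
  set.seed(9)
  n <- 500
  yy <- rnorm(n)
  xx1 <- 0.75 * yy + rnorm(n)
  xx2 <- rnorm(n)
  cmp <- bootstrap_compare_dependent_correlations(yy, xx1, xx2, seed = 2)
  expect_true(cmp$ci_low > 0)
  expect_true(cmp$significant)

  cmp2 <- bootstrap_compare_dependent_correlations(yy, xx1, xx2, seed = 2)
  expect_identical(cmp, cmp2)
  expect_error(bootstrap_compare_dependent_correlations(yy, xx1, xx2,
                                                        n_boot = 50),
               "n_boot")
})

test_that("Bonferroni correction divides alpha by the comparison count", {
  expect_identical(bonferroni_alpha(0.05, 2), 0.025)
  expect_identical(bonferroni_alpha(0.05, 1), 0.05)
  expect_error(bonferroni_alpha(0.05, 0), "m")
  expect_error(bonferroni_alpha(1.2, 2), "alpha")
})

test_that("frequentist results are invariant to monotone/affine maps", {
  set.seed(10)
  x <- rnorm(25); y <- 0.5 * x + rnorm(25)
  p1 <- pearson_directional(x, y, "greater", bayes = FALSE)
  p2 <- pearson_directional(2 * x + 3, 0.5 * y - 1, "greater",
                            bayes = FALSE)
  expect_equal(p1$estimate, p2$estimate, tolerance = 1e-12)
  expect_equal(p1$p, p2$p, tolerance = 1e-12)

  s1 <- spearman_directional(x, y, "greater", bayes = FALSE)
  s2 <- spearman_directional(exp(x), y^3 + y * 2, "greater", bayes = FALSE)
  expect_equal(s1$estimate, s2$estimate, tolerance = 1e-12)
})
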