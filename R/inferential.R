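# Directional frequentist correlation machinery: one-sided Pearson and
# Spearman tests, Steiger Z for dependent overlapping correlations, partial
# correlations, bootstrap comparison of dependent correlations, Bonferroni.

check_pair <- function(x, y, min_n = 4L) {
  stop_if(!is.numeric(x) || !is.numeric(y), "`x` and `y` must be numeric")
  stop_if(anyNA(x) || anyNA(y), "`x` and `y` must not contain missing values")
  stop_if(length(x) != length(y), "`x` and `y` must have equal length")
  stop_if(length(x) < min_n,
          sprintf("need at least %d paired observations", min_n))
  stop_if(stats::sd(x) == 0 || stats::sd(y) == 0,
          "correlation undefined: input is constant")
  invisible(NULL)
}

# one-sided p from the t transform of a correlation on df degrees of freedom
cor_t_pvalue <- function(est, df, alternative) {
  t_stat <- est * sqrt(df / (1 - est^2))
  switch(alternative,
         greater = stats::pt(t_stat, df, lower.tail = FALSE),
         less = stats::pt(t_stat, df),
         two_sided = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE))
}

cor_result <- function(estimate, n, alternative, p, method, df,
                       bayes, prior_width, ci_level) {
  out <- list(estimate = estimate, n = n, alternative = alternative, p = p,
              method = method, df = df, bf = NA_real_, bci_low = NA_real_,
              bci_high = NA_real_, prior_width = prior_width)
  if (bayes && abs(estimate) < 1) {
    bf <- default_bf_correlation(estimate, n, alternative, prior_width)
    bci <- posterior_credible_interval(bf$posterior, level = ci_level)
    out$bf <- bf$bf
    out$bci_low <- bci[1]
    out$bci_high <- bci[2]
  }
  structure(out, class = "cor_test_result")
}

#' @export
print.cor_test_result <- function(x, ...) {
  cat(sprintf("%s correlation: %.3f (n = %d), one-sided (%s) p = %.4g\n",
              x$method, x$estimate, x$n, x$alternative, x$p))
  if (!is.na(x$bf))
    cat(sprintf("  BF = %.4g, 95%% BCI [%.3f, %.3f]\n",
                x$bf, x$bci_low, x$bci_high))
  invisible(x)
}

#' Directional Pearson correlation with default Bayes factor
#'
#' Pearson correlation with a one-sided p-value from the exact t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom, plus,
#' optionally, the default correlation Bayes factor in the same direction
#' and a central 95% credible interval from the two-sided posterior.
#'
#' @param x,y Numeric vectors of equal length (n >= 4), neither constant.
#' @param alternative `"greater"` (predicted positive association),
#'   `"less"`, or `"two_sided"`.
#' @param bayes Compute the Bayes factor and credible interval? Default TRUE.
#' @param prior_width Stretched-beta prior width for the Bayes factor.
#' @param ci_level Credible-interval mass, default 0.95.
#'
#' @return A `cor_test_result` list: `estimate`, `n`, `alternative`, `p`,
#'   `bf`, `bci_low`, `bci_high`, `method`, `df`.
#' @export
pearson_directional <- function(x, y,
                                alternative = c("greater", "less",
                                                "two_sided"),
                                bayes = TRUE, prior_width = 1,
                                ci_level = 0.95) {
  alternative <- match.arg(alternative)
  check_pair(x, y)
  n <- length(x)
  r <- stats::cor(x, y)
  p <- cor_t_pvalue(r, n - 2, alternative)
  cor_result(r, n, alternative, p, "Pearson", n - 2, bayes, prior_width,
             ci_level)
}

#' Directional Spearman correlation
#'
#' Spearman's rho computed as the Pearson correlation of mid-ranks (average
#' ranks for ties), with a one-sided p-value from the t approximation on
#' \eqn{n-2} degrees of freedom.  The Bayes factor, when requested, applies
#' the default correlation Bayes factor to the rank correlation and should
#' be read as approximate.
#'
#' @inheritParams pearson_directional
#' @return A `cor_test_result` list; see [pearson_directional()].
#' @export
spearman_directional <- function(x, y,
                                 alternative = c("greater", "less",
                                                 "two_sided"),
                                 bayes = TRUE, prior_width = 1,
                                 ci_level = 0.95) {
  alternative <- match.arg(alternative)
  check_pair(x, y)
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  p <- cor_t_pvalue(rho, n - 2, alternative)
  cor_result(rho, n, alternative, p, "Spearman", n - 2, bayes, prior_width,
             ci_level)
}

#' Steiger Z test for two dependent overlapping correlations
#'
#' Compares the correlations of one variable j with each of two others k and
#' h measured on the same sample (Steiger, 1980, pooled-correlation
#' variant).  Both correlations are Fisher z-transformed and their
#' difference standardised using the asymptotic covariance evaluated at the
#' pooled correlation \eqn{\bar r = (r_{jk} + r_{jh})/2}:
#' \deqn{z = \frac{(z_{jk} - z_{jh})\sqrt{n - 3}}{\sqrt{2(1 - \bar s)}}}
#' where \eqn{\bar s = \psi / (1 - \bar r^2)^2} and
#' \eqn{\psi = r_{kh}(1 - 2\bar r^2) - \tfrac12 \bar r^2
#' (1 - 2\bar r^2 - r_{kh}^2)}.
#'
#' @param r_jk,r_jh The two overlapping correlations sharing variable j.
#' @param r_kh Correlation between the two non-shared variables.
#' @param n Sample size (>= 5).
#' @param alternative `"greater"` tests \eqn{r_{jk} > r_{jh}}; `"less"` and
#'   `"two_sided"` as usual.
#'
#' @return A `steiger_result` list: `z`, `p`, `n`, `r_jk`, `r_jh`, `r_kh`,
#'   `alternative`, `variant`.
#' @export
steiger_z_dependent <- function(r_jk, r_jh, r_kh, n,
                                alternative = c("greater", "less",
                                                "two_sided")) {
  alternative <- match.arg(alternative)
  for (nm in c("r_jk", "r_jh", "r_kh")) {
    v <- get(nm)
    check_number(v, nm)
    stop_if(abs(v) >= 1, sprintf("`%s` must lie strictly inside (-1, 1)", nm))
  }
  check_count(n, "n", lower = 5L)

  rbar <- (r_jk + r_jh) / 2
  psi <- r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)
  sbar <- psi / (1 - rbar^2)^2
  z <- (atanh(r_jk) - atanh(r_jh)) * sqrt(n - 3) / sqrt(2 * (1 - sbar))
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two_sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  structure(list(z = z, p = p, n = n, r_jk = r_jk, r_jh = r_jh, r_kh = r_kh,
                 alternative = alternative, variant = "steiger1980"),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf(
    "Steiger Z (dependent overlapping, %s): z = %.3f, p = %.4g (n = %d)\n",
    x$variant, x$z, x$p, x$n))
  invisible(x)
}

#' Directional partial correlation
#'
#' Partial correlation between `x` and `y` given covariates, computed as the
#' Pearson correlation of the OLS residuals of `x` and `y` on the covariates
#' (with intercept).  The one-sided p-value uses the t transform on
#' \eqn{n - 2 - k} degrees of freedom for k covariates.  A JZS Bayes factor
#' in the same direction is attached via [jzs_bf_partial_correlation()].
#'
#' @inheritParams jzs_bf_partial_correlation
#' @param bayes Attach a JZS Bayes factor? Default TRUE.
#'
#' @return A `partial_cor_result` list: `estimate`, `n`, `n_covariates`,
#'   `alternative`, `p`, `bf`.
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                alternative = c("greater", "less",
                                                "two_sided"),
                                bayes = TRUE) {
  alternative <- match.arg(alternative)
  check_pair(x, y)
  n <- length(x)
  Z <- prepare_covariates(covariates, n)
  k <- ncol(Z)
  stop_if(n <= k + 3, "need n > number of covariates + 3")
  X <- cbind(Intercept = rep(1, n), Z)
  stop_if(qr(X)$rank < ncol(X), "covariate design is rank deficient")

  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  est <- stats::cor(rx, ry)
  p <- cor_t_pvalue(est, n - 2 - k, alternative)
  bf <- if (bayes)
    jzs_bf_partial_correlation(x, y, covariates, alternative)$bf
  else NA_real_
  structure(list(estimate = est, n = n, n_covariates = k,
                 alternative = alternative, p = p, bf = bf),
            class = "partial_cor_result")
}

#' @export
print.partial_cor_result <- function(x, ...) {
  cat(sprintf(
    "Partial correlation: %.3f (n = %d, %d covariate%s), p = %.4g, BF = %.4g\n",
    x$estimate, x$n, x$n_covariates, if (x$n_covariates == 1) "" else "s",
    x$p, x$bf))
  invisible(x)
}

#' Bootstrap comparison of two dependent correlations
#'
#' Compares the magnitudes of corr(y, x1) and corr(y, x2) measured on the
#' same participants by resampling complete (y, x1, x2) triples with
#' replacement and forming the percentile confidence interval of the
#' difference corr(y, x1) - corr(y, x2) (Spearman by default, following
#' robust practice for comparing dependent correlations).
#'
#' @param y,x1,x2 Numeric vectors of equal length (n >= 10).
#' @param n_boot Number of bootstrap resamples (>= 100; default 1000).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param conf_level Confidence level of the percentile interval.
#' @param seed Optional integer seed; the global RNG state is left
#'   untouched.
#'
#' @return A `boot_cor_comparison` list: `observed` difference, `ci_low`,
#'   `ci_high`, `n_boot`, `significant` (interval excludes zero), `method`,
#'   `n`, `seed`.
#' @export
bootstrap_compare_dependent_correlations <- function(y, x1, x2,
                                                     n_boot = 1000L,
                                                     method = c("spearman",
                                                                "pearson"),
                                                     conf_level = 0.95,
                                                     seed = NULL) {
  method <- match.arg(method)
  check_pair(y, x1, min_n = 10L)
  check_pair(y, x2, min_n = 10L)
  check_count(n_boot, "n_boot", lower = 100L)
  n <- length(y)

  cor_fun <- if (method == "spearman")
    function(a, b) stats::cor(rank(a), rank(b))
  else stats::cor
  diff_of <- function(idx) {
    ys <- y[idx]; a <- x1[idx]; b <- x2[idx]
    if (stats::sd(ys) == 0 || stats::sd(a) == 0 || stats::sd(b) == 0)
      return(NA_real_)
    cor_fun(ys, a) - cor_fun(ys, b)
  }
  observed <- diff_of(seq_len(n))
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i)
    diff_of(sample.int(n, n, replace = TRUE)), numeric(1)))
  boots <- boots[!is.na(boots)]
  alpha <- (1 - conf_level) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
  structure(list(observed = observed, ci_low = ci[1], ci_high = ci[2],
                 n_boot = n_boot, n = n, method = method,
                 significant = ci[1] > 0 || ci[2] < 0, seed = seed),
            class = "boot_cor_comparison")
}

#' @export
print.boot_cor_comparison <- function(x, ...) {
  cat(sprintf(
    "Bootstrap difference of dependent %s correlations: %.3f, 95%% CI [%.3f, %.3f]%s\n",
    x$method, x$observed, x$ci_low, x$ci_high,
    if (x$significant) " (excludes 0)" else ""))
  invisible(x)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Nominal significance level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_alpha(0.05, 2)   # 0.025
#' @export
bonferroni_alpha <- function(alpha, m) {
  check_number(alpha, "alpha")
  stop_if(alpha <= 0 || alpha >= 1, "`alpha` must be in (0, 1)")
  check_count(m, "m")
  alpha / m
}
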