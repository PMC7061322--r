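# Per-participant learning-rate estimation: quadratic-trough cut-off,
# power-model fit on trials up to the cut-off, and the mean-latency
# alternative measure.

#' Data-driven learning-curve cut-off from a quadratic fit
#'
#' Fits latency on trial number with an ordinary least-squares second-order
#' polynomial over all trials.  When the parabola opens upward and its
#' vertex (the trough, where the first derivative crosses zero) falls inside
#' the usable trial range, the cut-off is the vertex rounded half-up to the
#' nearest trial; otherwise there is nothing to trim and all trials are
#' used.  The lower bound of 4 keeps at least four points for the
#' two-parameter power fit that follows.
#'
#' The vertex is invariant under positive affine transforms of the
#' latencies, so the cut-off does not depend on the latency units.
#'
#' @param latencies Numeric vector of per-trial latencies (seconds), trial
#'   index 1..n, n >= 4, all values in (0, t_max].
#' @param t_max Latency ceiling (seconds), default 60.
#'
#' @return A `quad_fit` list: `coefficients` (c0, c1, c2), `vertex` (real
#'   trial coordinate, NA when the parabola has no interior trough),
#'   `cutoff_trial`, `used_all_trials`, `n_trials`.
#' @export
fit_quadratic_cutoff <- function(latencies, t_max = 60) {
  check_series(latencies, t_max)
  n <- length(latencies)
  x <- seq_len(n)
  X <- cbind(1, x, x^2)
  cf <- stats::lm.fit(X, latencies)$coefficients
  names(cf) <- c("c0", "c1", "c2")

  vertex <- if (is.finite(cf[["c2"]]) && cf[["c2"]] > 0)
    -cf[["c1"]] / (2 * cf[["c2"]])
  else NA_real_
  in_range <- !is.na(vertex) && vertex >= 4 && vertex <= n
  cutoff <- if (in_range) as.integer(floor(vertex + 0.5)) else n

  structure(list(coefficients = cf, vertex = vertex,
                 cutoff_trial = cutoff, used_all_trials = !in_range,
                 n_trials = n),
            class = "quad_fit")
}

# closed-form log-log OLS of a power curve over trials 1..cutoff;
# returns c(a, b, r_squared).  Shared by the public fit and the fast
# permutation engine.
loglog_power_fit <- function(latencies, cutoff) {
  lx <- log(seq_len(cutoff))
  ly <- log(latencies[seq_len(cutoff)])
  sxx <- sum((lx - mean(lx))^2)
  syy <- sum((ly - mean(ly))^2)
  sxy <- sum((lx - mean(lx)) * (ly - mean(ly)))
  if (syy <= .Machine$double.eps * max(1, mean(ly)^2) * cutoff) {
    # flat series: zero slope, no variance explained
    return(c(a = exp(mean(ly)), b = 0, r_squared = 0))
  }
  b <- sxy / sxx
  a <- exp(mean(ly) - b * mean(lx))
  c(a = a, b = b, r_squared = sxy^2 / (sxx * syy))
}

#' Fit the power learning model to trials up to a cut-off
#'
#' Models latency as `time = a * x^b` over trials `x = 1..cutoff`, where the
#' exponent `b` indexes learning rate (more negative = faster learning).
#' The default `"loglog_ols"` method regresses log latency on log trial
#' number, which is closed-form and deterministic; `a` is the
#' back-transformed intercept and the coefficient of determination is
#' reported on the log-log scale.  `"nonlinear_ls"` refines that solution by
#' Levenberg-Marquardt least squares on the raw scale, with the coefficient
#' of determination recomputed on the raw scale.
#'
#' @param latencies Numeric latency vector (all positive).
#' @param cutoff Integer number of trials to model, 4 <= cutoff <= n.
#' @param method `"loglog_ols"` (default) or `"nonlinear_ls"`.
#' @param t_max Latency ceiling used for validation, default 60.
#'
#' @return A `power_fit` list: `a`, `b`, `r_squared`, `n_used`, `method`.
#' @export
fit_power_model <- function(latencies, cutoff,
                            method = c("loglog_ols", "nonlinear_ls"),
                            t_max = 60) {
  method <- match.arg(method)
  check_series(latencies, t_max)
  check_count(cutoff, "cutoff", lower = 4L)
  stop_if(cutoff > length(latencies),
          sprintf("`cutoff` (%d) exceeds the number of trials (%d)",
                  cutoff, length(latencies)))

  fit <- loglog_power_fit(latencies, cutoff)
  a <- fit[["a"]]
  b <- fit[["b"]]
  r2 <- fit[["r_squared"]]

  if (method == "nonlinear_ls") {
    x <- seq_len(cutoff)
    y <- latencies[x]
    nls_fit <- try(minpack.lm::nlsLM(y ~ a * x^b,
                                     start = list(a = a, b = b),
                                     control = minpack.lm::nls.lm.control(
                                       maxiter = 200)),
                   silent = TRUE)
    if (!inherits(nls_fit, "try-error")) {
      cf <- stats::coef(nls_fit)
      a <- cf[["a"]]
      b <- cf[["b"]]
      rss <- sum(stats::residuals(nls_fit)^2)
      tss <- sum((y - mean(y))^2)
      r2 <- if (tss > 0) max(0, 1 - rss / tss) else 0
    }
  }

  structure(list(a = a, b = b, r_squared = r2, n_used = as.integer(cutoff),
                 method = method),
            class = "power_fit")
}

#' Mean latency over trials up to the cut-off
#'
#' Arithmetic mean of the latencies for trials `1..cutoff`; the non-slope
#' alternative performance measure, usable also for participants excluded by
#' the behavioural screen.
#'
#' @inheritParams fit_power_model
#' @param cutoff Integer in `[1, n]`.
#' @return Mean latency in seconds.
#' @export
mean_latency_to_cutoff <- function(latencies, cutoff, t_max = 60) {
  check_series(latencies, t_max, min_len = 1L)
  check_count(cutoff, "cutoff")
  stop_if(cutoff > length(latencies),
          sprintf("`cutoff` (%d) exceeds the number of trials (%d)",
                  cutoff, length(latencies)))
  mean(latencies[seq_len(cutoff)])
}

#' Derive a participant's learning rate
#'
#' The full per-participant estimation chain: quadratic-trough cut-off,
#' power-model fit on trials up to the cut-off, and mean latency to the
#' cut-off.  Deterministic given the inputs.
#'
#' @inheritParams fit_power_model
#' @return A `learning_rate_result` list: `a`, `b`, `r_squared`, `cutoff`
#'   (a `quad_fit`), `cutoff_trial`, `mean_latency_to_cutoff`, `method`.
#' @export
derive_learning_rate <- function(latencies,
                                 method = c("loglog_ols", "nonlinear_ls"),
                                 t_max = 60) {
  method <- match.arg(method)
  quad <- fit_quadratic_cutoff(latencies, t_max)
  pw <- fit_power_model(latencies, quad$cutoff_trial, method, t_max)
  structure(list(a = pw$a, b = pw$b, r_squared = pw$r_squared,
                 cutoff = quad, cutoff_trial = quad$cutoff_trial,
                 mean_latency_to_cutoff =
                   mean_latency_to_cutoff(latencies, quad$cutoff_trial,
                                          t_max),
                 method = method),
            class = "learning_rate_result")
}

#' @export
print.learning_rate_result <- function(x, ...) {
  cat(sprintf(
    "Learning rate b = %.3f (a = %.1f s, R^2 = %.3f, trials 1..%d%s)\n",
    x$b, x$a, x$r_squared, x$cutoff_trial,
    if (x$cutoff$used_all_trials) ", no interior trough" else ""))
  cat(sprintf("Mean latency to cut-off: %.2f s\n", x$mean_latency_to_cutoff))
  invisible(x)
}
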