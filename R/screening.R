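# Behavioural screening (permutation null on learning-curve fit quality)
# and univariate MAD outlier filtering.

# Vectorised R^2 statistics for permuted latency series.  For each
# permutation the latencies are reordered, the quadratic-trough cut-off is
# re-derived (mode "full") or skipped (mode "all_trials"), and the log-log
# power-fit R^2 over trials 1..cutoff is computed from running sums -- the
# same closed-form statistic as loglog_power_fit(), evaluated for all
# permutations with matrix algebra rather than one model fit at a time.
perm_r2_null <- function(latencies, n_perm, pipeline_mode) {
  n <- length(latencies)
  x <- seq_len(n)
  lx <- log(x)
  csx <- cumsum(lx)
  csxx <- cumsum(lx^2)

  idx <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  Y <- matrix(latencies[idx], n, n_perm)

  if (pipeline_mode == "full") {
    X <- cbind(1, x, x^2)
    Pinv <- solve(crossprod(X), t(X))            # 3 x n projector
    cf <- Pinv %*% Y
    vertex <- -cf[2, ] / (2 * cf[3, ])
    k <- ifelse(cf[3, ] > 0 & !is.na(vertex) & vertex >= 4 & vertex <= n,
                floor(vertex + 0.5), n)
  } else {
    k <- rep(n, n_perm)
  }

  LY <- log(Y)
  Ltri <- matrix(0, n, n)
  Ltri[lower.tri(Ltri, diag = TRUE)] <- 1
  C1 <- Ltri %*% LY          # column cumsums of log latencies
  C2 <- Ltri %*% LY^2
  C3 <- Ltri %*% (lx * LY)

  pick <- cbind(k, seq_len(n_perm))
  sy <- C1[pick]; syy <- C2[pick]; sxy <- C3[pick]
  sx <- csx[k]; sxx <- csxx[k]
  num <- (k * sxy - sx * sy)^2
  d1 <- k * sxx - sx^2
  d2 <- k * syy - sy^2
  r2 <- ifelse(d2 > 1e-10 * pmax(1, syy), num / (d1 * d2), 0)
  pmin(pmax(r2, 0), 1)
}

#' Permutation null for a participant's learning-curve fit
#'
#' Tests whether a participant's power-model fit exceeds what trial-order
#' chance would produce.  The trial-wise latencies are shuffled `n_perm`
#' times; for each shuffle the fit statistic (log-log R^2) is recomputed,
#' either re-deriving the quadratic-trough cut-off first (`pipeline_mode =
#' "full"`, the default, so the null statistic matches the definition of the
#' observed one) or fitting all trials (`"all_trials"`).  The participant is
#' flagged for exclusion when the true R^2 does not exceed the upper edge of
#' the central `ci_level` interval of the null -- with the default 68%
#' interval, the empirical 84th percentile ("1 SD").  A `"mean_plus_sd"`
#' threshold (null mean + 1 null SD) is available as a variant.
#'
#' @inheritParams fit_power_model
#' @param n_perm Number of random permutations (>= 1; default 500).
#' @param pipeline_mode `"full"` or `"all_trials"`; see Details.
#' @param threshold_type `"percentile"` (default) or `"mean_plus_sd"`.
#' @param ci_level Central interval mass defining the percentile threshold;
#'   default 0.68.
#' @param seed Optional integer seed (global RNG state is preserved).
#' @param participant_id Optional identifier carried into the result.
#'
#' @return A `perm_null_result` list: `participant_id`, `true_r_squared`,
#'   `null_r_squared` (length `n_perm`), `threshold`, `threshold_type`,
#'   `excluded`, `n_perm`, `pipeline_mode`, `seed`.
#' @export
permutation_learning_null <- function(latencies, n_perm = 500L,
                                      pipeline_mode = c("full",
                                                        "all_trials"),
                                      threshold_type = c("percentile",
                                                         "mean_plus_sd"),
                                      ci_level = 0.68, t_max = 60,
                                      seed = NULL, participant_id = NA) {
  pipeline_mode <- match.arg(pipeline_mode)
  threshold_type <- match.arg(threshold_type)
  check_series(latencies, t_max)
  check_count(n_perm, "n_perm")
  check_number(ci_level, "ci_level")
  stop_if(ci_level <= 0 || ci_level >= 1, "`ci_level` must be in (0, 1)")

  true_r2 <- derive_learning_rate(latencies, t_max = t_max)$r_squared
  null_r2 <- with_seed(seed, perm_r2_null(latencies, n_perm, pipeline_mode))
  threshold <- if (threshold_type == "percentile")
    unname(stats::quantile(null_r2, 0.5 + ci_level / 2, type = 7))
  else mean(null_r2) + stats::sd(null_r2)

  structure(list(participant_id = participant_id,
                 true_r_squared = true_r2, null_r_squared = null_r2,
                 threshold = threshold, threshold_type = threshold_type,
                 excluded = true_r2 <= threshold,
                 n_perm = as.integer(n_perm),
                 pipeline_mode = pipeline_mode, seed = seed),
            class = "perm_null_result")
}

#' @export
print.perm_null_result <- function(x, ...) {
  cat(sprintf(
    "Permutation learning null (%d shuffles, %s): true R^2 = %.3f, threshold = %.3f -> %s\n",
    x$n_perm, x$pipeline_mode, x$true_r_squared, x$threshold,
    if (x$excluded) "EXCLUDED" else "retained"))
  invisible(x)
}

# coerce wide latency input (data.frame with participant_id, matrix, or
# list of numeric vectors) to a numeric matrix with one row per participant
as_latency_matrix <- function(latencies) {
  if (is.data.frame(latencies)) {
    ids <- if ("participant_id" %in% names(latencies))
      as.character(latencies$participant_id)
    else as.character(seq_len(nrow(latencies)))
    m <- as.matrix(latencies[setdiff(names(latencies), "participant_id")])
    rownames(m) <- ids
  } else if (is.matrix(latencies)) {
    m <- latencies
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  } else if (is.list(latencies)) {
    m <- do.call(rbind, latencies)
    rownames(m) <- if (!is.null(names(latencies))) names(latencies)
    else as.character(seq_along(latencies))
  } else {
    stop("latencies must be a data frame, matrix, or list of series",
         call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

#' Flag participants without behavioural evidence of learning
#'
#' Applies [permutation_learning_null()] to every participant of a cohort.
#' Each participant draws their permutations from an independent
#' L'Ecuyer-CMRG substream of the master seed, so results are reproducible
#' and unchanged for existing participants when the cohort grows.
#'
#' @param latencies Wide latency table: a data frame with a
#'   `participant_id` column and one column per trial (as produced by
#'   [simulate_cohort()] or [read_latency_table()]), a numeric matrix
#'   (participants x trials), or a list of latency vectors.
#' @inheritParams permutation_learning_null
#' @param seed Master seed (integer) for the permutation substreams.
#'
#' @return A data frame with one row per participant: `participant_id`,
#'   `true_r2`, `threshold`, `excluded`.  The full per-participant
#'   `perm_null_result` objects are attached as attribute `"details"`.
#' @export
flag_nonlearners <- function(latencies, n_perm = 500L,
                             pipeline_mode = c("full", "all_trials"),
                             threshold_type = c("percentile",
                                                "mean_plus_sd"),
                             ci_level = 0.68, t_max = 60, seed = 1L) {
  pipeline_mode <- match.arg(pipeline_mode)
  threshold_type <- match.arg(threshold_type)
  m <- as_latency_matrix(latencies)
  stop_if(nrow(m) < 1L, "cohort must contain at least one participant")

  streams <- rng_streams(seed, nrow(m))
  details <- lapply(seq_len(nrow(m)), function(i) {
    with_rng_stream(streams[[i]], {
      res <- permutation_learning_null(
        m[i, ], n_perm = n_perm, pipeline_mode = pipeline_mode,
        threshold_type = threshold_type, ci_level = ci_level,
        t_max = t_max, seed = NULL, participant_id = rownames(m)[i])
      res$seed <- seed
      res
    })
  })
  out <- data.frame(
    participant_id = rownames(m),
    true_r2 = vapply(details, `[[`, numeric(1), "true_r_squared"),
    threshold = vapply(details, `[[`, numeric(1), "threshold"),
    excluded = vapply(details, `[[`, logical(1), "excluded"),
    stringsAsFactors = FALSE)
  attr(out, "details") <- details
  out
}

#' Median-absolute-deviation outlier filter
#'
#' Two-sided univariate outlier screen: values farther than `threshold`
#' scaled MADs from the median are flagged for removal.  The scaled MAD is
#' `consistency_constant * median(|x - median(x)|)`; the default constant
#' 1.4826 makes it a consistent estimator of the standard deviation under
#' normality.  When the MAD is zero, only values equal to the median are
#' kept.
#'
#' @param values Numeric vector of at least 3 finite values.
#' @param threshold Number of scaled MADs defining the bounds; default 2.5.
#' @param consistency_constant Scale factor for the raw MAD; default 1.4826.
#'
#' @return An `outlier_mask` list: `values`, `median`, `mad_scaled`,
#'   `lower`, `upper`, `keep` (logical vector).
#' @export
mad_outlier_filter <- function(values, threshold = 2.5,
                               consistency_constant = 1.4826) {
  stop_if(!is.numeric(values), "`values` must be numeric")
  stop_if(any(!is.finite(values)), "`values` must be finite")
  stop_if(length(values) < 3L, "need at least 3 values")
  check_number(threshold, "threshold")
  stop_if(threshold <= 0, "`threshold` must be positive")
  check_number(consistency_constant, "consistency_constant")
  stop_if(consistency_constant <= 0,
          "`consistency_constant` must be positive")

  med <- stats::median(values)
  mad_scaled <- stats::mad(values, constant = consistency_constant)
  lower <- med - threshold * mad_scaled
  upper <- med + threshold * mad_scaled
  structure(list(values = values, median = med, mad_scaled = mad_scaled,
                 lower = lower, upper = upper,
                 keep = values >= lower & values <= upper),
            class = "outlier_mask")
}

#' @export
print.outlier_mask <- function(x, ...) {
  cat(sprintf(
    "MAD outlier filter: median %.4g, scaled MAD %.4g, bounds [%.4g, %.4g]; removed %d of %d\n",
    x$median, x$mad_scaled, x$lower, x$upper, sum(!x$keep),
    length(x$keep)))
  invisible(x)
}
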