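# Orchestration of the full analysis: simulate/load -> learning-rate
# fits -> behavioural and outlier screening -> directional correlation
# suite -> report.

#' Configuration for a full analysis run
#'
#' Validates and bundles every setting of the pipeline.  The defaults
#' mirror the analysis protocol the package implements: 500 permutations
#' for the behavioural screen with a 68% central-interval (84th percentile)
#' threshold, a 2.5-MAD outlier filter per tract metric, and a Bonferroni
#' correction of alpha = .05 over 2 comparisons per metric.
#'
#' @param latency_file,metrics_file CSV paths (see [read_latency_table()]
#'   and [read_metrics_table()]); alternatively supply `params` to
#'   simulate.
#' @param params A [cohort_params()] object to generate a synthetic cohort
#'   instead of reading files.
#' @param fit_method Power-fit method, `"loglog_ols"` or `"nonlinear_ls"`.
#' @param n_perm Permutations for the behavioural screen; default 500.
#' @param ci_level Central-interval mass for the permutation threshold;
#'   default 0.68.
#' @param threshold_type `"percentile"` or `"mean_plus_sd"`.
#' @param pipeline_mode Permutation statistic mode; see
#'   [permutation_learning_null()].
#' @param mad_threshold MAD multiple for the outlier filter; default 2.5.
#' @param alpha Nominal significance level; default 0.05.
#' @param comparisons_per_metric Comparisons entering the Bonferroni
#'   correction; default 2.
#' @param n_boot Bootstrap resamples for the dependent-correlation
#'   comparison; default 1000.
#' @param include_excluded_in_mean_latency Re-admit behaviourally excluded
#'   participants into the mean-latency analyses? Default FALSE.
#' @param t_max Latency ceiling in seconds; default 60.
#' @param seed Master seed controlling every stochastic stage.
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(latency_file = NULL, metrics_file = NULL,
                            params = NULL, fit_method = c("loglog_ols",
                                                          "nonlinear_ls"),
                            n_perm = 500L, ci_level = 0.68,
                            threshold_type = c("percentile",
                                               "mean_plus_sd"),
                            pipeline_mode = c("full", "all_trials"),
                            mad_threshold = 2.5, alpha = 0.05,
                            comparisons_per_metric = 2L, n_boot = 1000L,
                            include_excluded_in_mean_latency = FALSE,
                            t_max = 60, seed = 1L) {
  fit_method <- match.arg(fit_method)
  threshold_type <- match.arg(threshold_type)
  pipeline_mode <- match.arg(pipeline_mode)
  has_files <- !is.null(latency_file) && !is.null(metrics_file)
  stop_if(is.null(params) && !has_files,
          "supply either `params` or both `latency_file` and `metrics_file`")
  stop_if(!is.null(params) && !inherits(params, "cohort_params"),
          "`params` must be a cohort_params object")
  check_count(n_perm, "n_perm")
  check_number(ci_level, "ci_level")
  stop_if(ci_level <= 0 || ci_level >= 1, "`ci_level` must be in (0, 1)")
  check_number(mad_threshold, "mad_threshold")
  stop_if(mad_threshold <= 0, "`mad_threshold` must be positive")
  check_number(alpha, "alpha")
  stop_if(alpha <= 0 || alpha >= 1, "`alpha` must be in (0, 1)")
  check_count(comparisons_per_metric, "comparisons_per_metric")
  check_count(n_boot, "n_boot", lower = 100L)
  check_count(seed, "seed", lower = 0L)

  structure(list(latency_file = latency_file, metrics_file = metrics_file,
                 params = params, fit_method = fit_method,
                 n_perm = as.integer(n_perm), ci_level = ci_level,
                 threshold_type = threshold_type,
                 pipeline_mode = pipeline_mode,
                 mad_threshold = mad_threshold, alpha = alpha,
                 comparisons_per_metric = as.integer(comparisons_per_metric),
                 n_boot = as.integer(n_boot),
                 include_excluded_in_mean_latency =
                   isTRUE(include_excluded_in_mean_latency),
                 t_max = t_max, seed = as.integer(seed)),
            class = "analysis_config")
}

# predicted direction of association with worse performance (higher b,
# longer latency): MD positive, FA negative
metric_direction <- function(metric) {
  if (grepl("_md$", metric)) "greater" else "less"
}

#' Run the full navigational-learning analysis
#'
#' Executes the complete pipeline: load or simulate the cohort, derive each
#' participant's learning rate (quadratic-trough cut-off + power fit),
#' exclude participants whose fit does not beat their own permutation null,
#' filter univariate outliers per tract metric with the MAD rule, and run
#' the directional correlation suite -- one-sided Pearson and Spearman with
#' default Bayes factors and credible intervals for every (behavioural
#' measure, tract metric) pair in the predicted direction (MD positive, FA
#' negative), Steiger Z and bootstrap comparisons of fornix versus ILF
#' within each metric class, and partial correlations controlling
#' proportional hippocampal volume and, separately, gender.  Everything is
#' reproducible from the master seed.
#'
#' @param config An [analysis_config()] object.
#' @return A list of class `nav_report`; see [write_report()].
#' @export
run_full_analysis <- function(config) {
  stop_if(!inherits(config, "analysis_config"),
          "`config` must come from analysis_config()")

  # --- load or simulate -------------------------------------------------
  truth <- NULL
  if (!is.null(config$params)) {
    cohort <- simulate_cohort(config$params)
    latencies <- cohort$latencies
    metrics <- cohort$metrics
    truth <- cohort$truth
  } else {
    latencies <- read_latency_table(config$latency_file, config$t_max)
    metrics <- read_metrics_table(config$metrics_file)
  }
  stop_if(!setequal(latencies$participant_id, metrics$participant_id),
          "latency and metrics tables cover different participants")
  metrics <- metrics[match(latencies$participant_id,
                           metrics$participant_id), ]
  metrics$prop_hc_volume <- proportional_volume(metrics$hippocampal_volume,
                                                metrics$etiv)

  # --- per-participant learning rates ----------------------------------
  lat_mat <- as_latency_matrix(latencies)
  fits <- lapply(seq_len(nrow(lat_mat)), function(i)
    derive_learning_rate(lat_mat[i, ], method = config$fit_method,
                         t_max = config$t_max))
  learning <- data.frame(
    participant_id = rownames(lat_mat),
    a = vapply(fits, `[[`, numeric(1), "a"),
    b = vapply(fits, `[[`, numeric(1), "b"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    cutoff_trial = vapply(fits, `[[`, integer(1), "cutoff_trial"),
    used_all_trials = vapply(fits, function(f) f$cutoff$used_all_trials,
                             logical(1)),
    mean_latency = vapply(fits, `[[`, numeric(1),
                          "mean_latency_to_cutoff"),
    stringsAsFactors = FALSE)

  # --- behavioural screen ----------------------------------------------
  screening <- flag_nonlearners(latencies, n_perm = config$n_perm,
                                pipeline_mode = config$pipeline_mode,
                                threshold_type = config$threshold_type,
                                ci_level = config$ci_level,
                                t_max = config$t_max, seed = config$seed)
  attr(screening, "details") <- NULL

  cohort_table <- cbind(learning,
                        screening[match(learning$participant_id,
                                        screening$participant_id),
                                  c("true_r2", "threshold", "excluded")],
                        metrics[, setdiff(names(metrics),
                                          "participant_id")])
  if (!is.null(truth))
    cohort_table <- cbind(cohort_table,
                          truth[match(cohort_table$participant_id,
                                      truth$participant_id),
                                c("true_a", "true_b", "true_plateau",
                                  "is_learner")])
  rownames(cohort_table) <- NULL

  metrics_of_interest <- c("fornix_md", "fornix_fa", "ilf_md", "ilf_fa")
  measures <- c("b", "mean_latency")
  retained <- !cohort_table$excluded

  # rows entering the analysis of a given measure, before outlier removal
  measure_base <- function(measure) {
    if (measure == "mean_latency" &&
          config$include_excluded_in_mean_latency)
      rep(TRUE, nrow(cohort_table))
    else retained
  }

  # --- per-metric MAD screens on behaviourally retained participants ---
  outliers <- lapply(metrics_of_interest, function(metric) {
    mask <- mad_outlier_filter(cohort_table[[metric]][retained],
                               threshold = config$mad_threshold)
    list(metric = metric, n_checked = sum(retained),
         lower = mask$lower, upper = mask$upper,
         removed_ids =
           cohort_table$participant_id[retained][!mask$keep])
  })
  names(outliers) <- metrics_of_interest
  metric_keep <- function(metric)
    !(cohort_table$participant_id %in% outliers[[metric]]$removed_ids)

  # --- directional zero-order correlations ------------------------------
  correlations <- list()
  for (measure in measures) {
    for (metric in metrics_of_interest) {
      rows <- measure_base(measure) & metric_keep(metric)
      y <- cohort_table[[measure]][rows]
      m <- cohort_table[[metric]][rows]
      dir <- metric_direction(metric)
      for (fun in c("pearson", "spearman")) {
        res <- if (fun == "pearson")
          pearson_directional(y, m, dir)
        else spearman_directional(y, m, dir)
        correlations[[length(correlations) + 1L]] <- data.frame(
          measure = measure, metric = metric, method = res$method,
          alternative = dir, n = res$n, estimate = res$estimate,
          p = res$p, bf = res$bf, bci_low = res$bci_low,
          bci_high = res$bci_high, stringsAsFactors = FALSE)
      }
    }
  }
  correlations <- do.call(rbind, correlations)

  # --- fornix vs ILF comparisons per metric class ----------------------
  comparisons <- list()
  boot_seed_base <- config$seed + 1000L
  for (measure in measures) {
    for (class_suffix in c("md", "fa")) {
      fornix <- paste0("fornix_", class_suffix)
      ilf <- paste0("ilf_", class_suffix)
      rows <- measure_base(measure) & metric_keep(fornix) &
        metric_keep(ilf)
      y <- cohort_table[[measure]][rows]
      x1 <- cohort_table[[fornix]][rows]
      x2 <- cohort_table[[ilf]][rows]
      dir <- metric_direction(fornix)
      st <- steiger_z_dependent(stats::cor(y, x1), stats::cor(y, x2),
                                stats::cor(x1, x2), length(y), dir)
      bt <- bootstrap_compare_dependent_correlations(
        y, x1, x2, n_boot = config$n_boot,
        seed = boot_seed_base + length(comparisons))
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        measure = measure, metric_class = class_suffix, n = length(y),
        r_fornix = st$r_jk, r_ilf = st$r_jh, r_between = st$r_kh,
        steiger_z = st$z, steiger_p = st$p, boot_diff = bt$observed,
        boot_ci_low = bt$ci_low, boot_ci_high = bt$ci_high,
        boot_excludes_zero = bt$significant, stringsAsFactors = FALSE)
    }
  }
  comparisons <- do.call(rbind, comparisons)

  # --- partial correlations --------------------------------------------
  partials <- list()
  for (measure in measures) {
    for (metric in metrics_of_interest) {
      for (covariate in c("prop_hc_volume", "gender")) {
        rows <- measure_base(measure) & metric_keep(metric)
        if (covariate == "gender" &&
              length(unique(cohort_table$gender[rows])) < 2) next
        pc <- partial_correlation(cohort_table[[measure]][rows],
                                  cohort_table[[metric]][rows],
                                  cohort_table[[covariate]][rows],
                                  metric_direction(metric))
        partials[[length(partials) + 1L]] <- data.frame(
          measure = measure, metric = metric, covariate = covariate,
          n = pc$n, estimate = pc$estimate, p = pc$p, bf = pc$bf,
          stringsAsFactors = FALSE)
      }
    }
  }
  partials <- do.call(rbind, partials)

  settings <- unclass(config)
  settings$params <- if (!is.null(config$params))
    unclass(config$params)
  else NULL

  structure(list(
    schema_version = "1.0",
    settings = settings,
    seed = config$seed,
    alpha = config$alpha,
    alpha_corrected = bonferroni_alpha(config$alpha,
                                       config$comparisons_per_metric),
    learning = learning,
    screening = screening,
    outliers = outliers,
    cohort = cohort_table,
    correlations = correlations,
    comparisons = comparisons,
    partials = partials),
    class = "nav_report")
}

#' @export
print.nav_report <- function(x, ...) {
  cat(sprintf(
    "Navigational-learning analysis report (seed %d)\n", x$seed))
  cat(sprintf("  %d participants, %d excluded by the behavioural screen\n",
              nrow(x$screening), sum(x$screening$excluded)))
  cat(sprintf("  Bonferroni-corrected alpha: %.4g\n", x$alpha_corrected))
  cat("\nZero-order correlations (Pearson rows):\n")
  pr <- x$correlations[x$correlations$method == "Pearson", ]
  print(pr[, c("measure", "metric", "n", "estimate", "p", "bf")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

report_required_fields <- c("schema_version", "settings", "seed", "alpha",
                            "alpha_corrected", "learning", "screening",
                            "outliers", "cohort", "correlations",
                            "comparisons", "partials")

#' Write an analysis report to disk
#'
#' Serialises a `nav_report` as `report.json` (full numeric precision) plus
#' the cohort table as `cohort.csv`, after validating that every pipeline
#' stage is present.  Optionally renders the per-participant learning
#' curves with their power fits to `learning_curves.pdf`.
#'
#' @param report A `nav_report` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @param plots Also write the learning-curve figure? Default FALSE.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, plots = FALSE) {
  stop_if(!inherits(report, "nav_report"),
          "`report` must come from run_full_analysis()")
  missing <- setdiff(report_required_fields, names(report))
  stop_if(length(missing) > 0,
          sprintf("report fails schema validation; missing: %s",
                  paste(missing, collapse = ", ")))
  lapply(report_required_fields, function(f)
    stop_if(is.null(report[[f]]),
            sprintf("report fails schema validation; `%s` is empty", f)))

  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  csv_path <- file.path(dir, "cohort.csv")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  utils::write.csv(report$cohort, csv_path, row.names = FALSE)
  paths <- c(json_path, csv_path)
  if (plots) {
    pdf_path <- file.path(dir, "learning_curves.pdf")
    grDevices::pdf(pdf_path, width = 10, height = 8)
    on.exit(grDevices::dev.off())
    plot_learning_curves(report)
    paths <- c(paths, pdf_path)
  }
  invisible(paths)
}

#' Plot per-participant learning curves with power fits
#'
#' Draws trial latencies for up to `max_panels` participants with the
#' fitted power curve over the modelled trials (solid to the cut-off) and
#' the group-mean curve in the first panel.  Deterministic: no random
#' numbers are consumed.
#'
#' @param report A `nav_report` object.
#' @param participants Optional character vector of participant ids.
#' @param max_panels Maximum number of per-participant panels; default 24.
#' @return Invisibly, `NULL`.
#' @export
plot_learning_curves <- function(report, participants = NULL,
                                 max_panels = 24L) {
  stop_if(!inherits(report, "nav_report"),
          "`report` must come from run_full_analysis()")
  lrn <- report$learning
  if (is.null(participants)) participants <- lrn$participant_id
  participants <- utils::head(participants, max_panels)

  trial_cols <- grep("^trial_", names(report$cohort), value = TRUE)
  # cohort table lacks raw latencies; reconstruct the group curve from
  # fitted values when they are absent
  old_par <- graphics::par(mfrow = c(ceiling((length(participants) + 1) / 5),
                                     5),
                           mar = c(2.5, 2.5, 1.5, 0.5), mgp = c(1.4, .4, 0))
  on.exit(graphics::par(old_par))

  graphics::plot(NA, xlim = c(1, max(lrn$cutoff_trial)),
                 ylim = c(0, max(lrn$a)), xlab = "trial",
                 ylab = "latency (s)", main = "fitted curves (all)")
  for (i in seq_len(nrow(lrn))) {
    xs <- seq(1, lrn$cutoff_trial[i], length.out = 50)
    graphics::lines(xs, lrn$a[i] * xs^lrn$b[i],
                    col = grDevices::grey(0.2, 0.35))
  }
  for (pid in participants) {
    i <- match(pid, lrn$participant_id)
    xs <- seq(1, lrn$cutoff_trial[i], length.out = 50)
    graphics::plot(xs, lrn$a[i] * xs^lrn$b[i], type = "l", col = "red3",
                   xlab = "trial", ylab = "latency (s)", main = pid)
  }
  invisible(NULL)
}
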