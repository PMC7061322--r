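# CSV readers/writers for latency and metrics tables, and the
# proportional-volume covariate.

#' Read a wide per-participant latency table
#'
#' Expects a CSV with header `participant_id, trial_01, ..., trial_NN` and
#' one row per participant.  Every latency cell must be numeric, present,
#' positive, and no larger than `t_max`; violations raise an error naming
#' the offending row and column.
#'
#' @param path Path to the CSV file.
#' @param t_max Latency ceiling in seconds; default 60.
#' @return A data frame with `participant_id` (character) and one numeric
#'   column per trial.
#' @export
read_latency_table <- function(path, t_max = 60) {
  stop_if(!file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  stop_if(names(df)[1] != "participant_id",
          "latency table must start with a `participant_id` column")
  trial_cols <- names(df)[-1]
  stop_if(length(trial_cols) < 4L,
          "latency table needs at least 4 trial columns")
  stop_if(!all(grepl("^trial_[0-9]+$", trial_cols)),
          "trial columns must be named trial_01, trial_02, ...")
  stop_if(anyDuplicated(df$participant_id) > 0,
          "duplicated participant_id values")

  for (cl in trial_cols) {
    v <- df[[cl]]
    if (!is.numeric(v))
      stop(sprintf("column %s is not numeric", cl), call. = FALSE)
    bad <- which(is.na(v) | v <= 0 | v > t_max)
    if (length(bad) > 0)
      stop(sprintf(
        "invalid latency at row %d (participant %s), column %s: %s (must be in (0, %s])",
        bad[1], df$participant_id[bad[1]], cl, v[bad[1]], t_max),
        call. = FALSE)
  }
  df$participant_id <- as.character(df$participant_id)
  df
}

#' Read a per-participant metrics table
#'
#' Expects a CSV with tract diffusion metrics, volumes and gender.  ILF
#' metrics may be supplied either bilaterally (`ilf_fa`, `ilf_md`) or per
#' hemisphere (`ilf_fa_left`/`ilf_fa_right`, `ilf_md_left`/
#' `ilf_md_right`), in which case the hemispheric values are averaged into
#' a bilateral measure.  FA values must lie in (0, 1); MD values (in 10^-3
#' mm^2/s) and volumes (mm^3) must be positive.  Gender may be numeric 0/1
#' or coded strings translated through `gender_map`.
#'
#' @param path Path to the CSV file.
#' @param gender_map Named numeric vector mapping string codes to 0/1;
#'   default `c(F = 0, M = 1)`.
#' @return A validated data frame with columns `participant_id`,
#'   `fornix_fa`, `fornix_md`, `ilf_fa`, `ilf_md`, `hippocampal_volume`,
#'   `etiv`, `gender`.
#' @export
read_metrics_table <- function(path, gender_map = c("F" = 0, "M" = 1)) {
  stop_if(!file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if(!"participant_id" %in% names(df),
          "metrics table must contain `participant_id`")

  for (side_metric in c("ilf_fa", "ilf_md")) {
    l <- paste0(side_metric, "_left")
    r <- paste0(side_metric, "_right")
    if (!side_metric %in% names(df) && all(c(l, r) %in% names(df)))
      df[[side_metric]] <- (df[[l]] + df[[r]]) / 2
  }
  required <- c("fornix_fa", "fornix_md", "ilf_fa", "ilf_md",
                "hippocampal_volume", "etiv", "gender")
  missing <- setdiff(required, names(df))
  stop_if(length(missing) > 0,
          sprintf("missing required column(s): %s",
                  paste(missing, collapse = ", ")))

  if (is.character(df$gender)) {
    stop_if(!all(df$gender %in% names(gender_map)),
            sprintf("gender codes outside mapping {%s}",
                    paste(names(gender_map), collapse = ", ")))
    df$gender <- unname(gender_map[df$gender])
  }
  stop_if(!all(df$gender %in% c(0, 1)), "gender must be coded 0/1")

  for (cl in c("fornix_fa", "ilf_fa")) {
    v <- df[[cl]]
    stop_if(!is.numeric(v) || anyNA(v) || any(v <= 0 | v >= 1),
            sprintf("%s values must lie in (0, 1)", cl))
  }
  for (cl in c("fornix_md", "ilf_md", "hippocampal_volume", "etiv")) {
    v <- df[[cl]]
    stop_if(!is.numeric(v) || anyNA(v) || any(v <= 0),
            sprintf("%s values must be positive", cl))
  }
  df$participant_id <- as.character(df$participant_id)
  df[c("participant_id", required)]
}

#' Proportional hippocampal volume
#'
#' Divides a structure volume by estimated total intracranial volume
#' (eTIV), yielding the dimensionless proportional score used as a
#' covariate.  A ratio of 1 or more is anatomically implausible and raises
#' a warning.
#'
#' @param volume Structure volume(s), mm^3 (> 0).
#' @param etiv Estimated total intracranial volume(s), mm^3 (> 0).
#' @return `volume / etiv`.
#' @examples
#' proportional_volume(8000, 1600000)   # 0.005
#' @export
proportional_volume <- function(volume, etiv) {
  stop_if(!is.numeric(volume) || !is.numeric(etiv) ||
            anyNA(volume) || anyNA(etiv),
          "`volume` and `etiv` must be numeric and non-missing")
  stop_if(any(volume <= 0) || any(etiv <= 0),
          "`volume` and `etiv` must be positive")
  ratio <- volume / etiv
  if (any(ratio >= 1))
    warning("proportional volume >= 1: implausible anatomy",
            call. = FALSE)
  ratio
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `latencies.csv` (wide format read back by
#' [read_latency_table()]), `metrics.csv` ([read_metrics_table()]) and
#' `truth.csv` (the generator's ground truth) into a directory.
#'
#' @param cohort A `nav_cohort` object from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stop_if(!inherits(cohort, "nav_cohort"),
          "`cohort` must come from simulate_cohort()")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("latencies.csv", "metrics.csv", "truth.csv"))
  utils::write.csv(cohort$latencies, paths[1], row.names = FALSE)
  utils::write.csv(cohort$metrics, paths[2], row.names = FALSE)
  utils::write.csv(cohort$truth, paths[3], row.names = FALSE)
  invisible(paths)
}
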