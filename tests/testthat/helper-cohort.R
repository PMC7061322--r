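# shared fixtures, built in code

# exact power-law series (no noise, no ceiling)
power_series <- function(a, b, n = 20) a * seq_len(n)^b

# i.i.d. (exchangeable) latency series capped at the trial ceiling
iid_series <- function(n = 20, t_max = 60, meanlog = log(30), sdlog = 0.4) {
  pmin(t_max, exp(stats::rnorm(n, meanlog, sdlog)))
}

# matrix of i.i.d.-latency participants
iid_cohort <- function(n_participants, n_trials = 20, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed(t(replicate(n_participants, iid_series(n_trials))))
}

# small metrics CSV written to a temp file, returning the path
write_metrics_fixture <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

metrics_fixture_df <- function(n = 6, seed = 99) {
  set.seed(seed)
  data.frame(participant_id = sprintf("S%02d", seq_len(n)),
             fornix_fa = runif(n, 0.35, 0.55),
             fornix_md = runif(n, 0.7, 0.9),
             ilf_fa = runif(n, 0.4, 0.55),
             ilf_md = runif(n, 0.7, 0.85),
             hippocampal_volume = runif(n, 7000, 9000),
             etiv = runif(n, 1.3e6, 1.7e6),
             gender = rep(c(0, 1), length.out = n))
}
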