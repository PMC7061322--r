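# Synthetic cohort generator: latency series with power-law improvement and
# an early plateau, tract metrics with a controllable correlation to the
# true learning rate, covariates, and a simple arena navigation agent.

#' Parameters of a synthetic navigation cohort
#'
#' Bundles and validates the generative settings used by
#' [simulate_cohort()].  Defaults emulate a 20-trial virtual water-maze
#' session with a 60-second trial ceiling, per-participant learning
#' exponents drawn from Normal(-0.32, 0.08) truncated to negative values,
#' initial latencies between 35 and 60 s, plateau onset uniform between
#' trials 7 and 20, and lognormal trial noise that is small during
#' acquisition (`noise_sd`) and large after the plateau (`late_noise_sd`),
#' reflecting the variable or slow late-trial behaviour of fast learners.
#'
#' @param n_participants Number of participants (>= 1).
#' @param n_trials Trials per participant (>= 4; default 20).
#' @param t_max Latency ceiling in seconds (default 60).
#' @param b_mean,b_sd Population mean (< 0) and SD (> 0) of the learning
#'   exponent b; defaults -0.32 and 0.08.
#' @param a_range Range of the initial-latency scale a in seconds; default
#'   `c(35, 60)`.
#' @param plateau_range Integer range of plateau-onset trials; default
#'   `c(7, 20)`.
#' @param noise_sd Log-latency noise SD before the plateau; default 0.06.
#' @param late_noise_sd Log-latency noise SD after the plateau; default
#'   0.45.
#' @param target_r_fornix_md Population correlation between fornix MD and
#'   the true learning exponent; default 0.44.
#' @param target_r_ilf_md As above for ILF MD; default 0 (comparison tract).
#' @param fa_md_coupling Within-tract correlation between FA and MD noise
#'   components; default -0.5, which at the default MD target induces a
#'   fornix FA correlation with b of about -0.22 without a separate dial.
#' @param nonlearner_fraction Expected fraction of participants whose
#'   latencies are trend-free i.i.d. draws (no learning); default 0.15.
#' @param p_female Probability of gender code 0 (female); default 0.5.
#' @param seed Master RNG seed; default 1.
#'
#' @return A validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_participants, n_trials = 20L, t_max = 60,
                          b_mean = -0.32, b_sd = 0.08,
                          a_range = c(35, 60), plateau_range = c(7L, 20L),
                          noise_sd = 0.06, late_noise_sd = 0.45,
                          target_r_fornix_md = 0.44, target_r_ilf_md = 0,
                          fa_md_coupling = -0.5, nonlearner_fraction = 0.15,
                          p_female = 0.5, seed = 1L) {
  check_count(n_participants, "n_participants")
  check_count(n_trials, "n_trials", lower = 4L)
  check_number(t_max, "t_max")
  stop_if(t_max <= 0, "`t_max` must be positive")
  check_number(b_mean, "b_mean", upper = 0)
  stop_if(b_mean >= 0, "`b_mean` must be negative")
  check_number(b_sd, "b_sd")
  stop_if(b_sd <= 0, "`b_sd` must be positive")
  stop_if(length(a_range) != 2L || any(a_range <= 0) || diff(a_range) < 0,
          "`a_range` must be an increasing pair of positive values")
  stop_if(length(plateau_range) != 2L || diff(plateau_range) < 0 ||
            plateau_range[1] < 1 || plateau_range[2] > n_trials,
          "`plateau_range` must be an increasing pair within [1, n_trials]")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(late_noise_sd, "late_noise_sd", lower = 0)
  check_number(target_r_fornix_md, "target_r_fornix_md")
  check_number(target_r_ilf_md, "target_r_ilf_md")
  stop_if(abs(target_r_fornix_md) >= 1 || abs(target_r_ilf_md) >= 1,
          "target correlations must lie strictly inside (-1, 1)")
  check_number(fa_md_coupling, "fa_md_coupling")
  stop_if(abs(fa_md_coupling) >= 1,
          "`fa_md_coupling` must lie strictly inside (-1, 1)")
  check_number(nonlearner_fraction, "nonlearner_fraction", lower = 0,
               upper = 1)
  check_number(p_female, "p_female", lower = 0, upper = 1)
  check_count(seed, "seed", lower = 0L)

  structure(list(n_participants = as.integer(n_participants),
                 n_trials = as.integer(n_trials), t_max = t_max,
                 b_mean = b_mean, b_sd = b_sd, a_range = a_range,
                 plateau_range = as.integer(plateau_range),
                 noise_sd = noise_sd, late_noise_sd = late_noise_sd,
                 target_r_fornix_md = target_r_fornix_md,
                 target_r_ilf_md = target_r_ilf_md,
                 fa_md_coupling = fa_md_coupling,
                 nonlearner_fraction = nonlearner_fraction,
                 p_female = p_female, seed = as.integer(seed)),
            class = "cohort_params")
}

#' Simulate one participant's latency series
#'
#' Latencies follow `min(t_max, a * x^b * exp(eps))` for trials up to the
#' plateau, with `eps ~ Normal(0, noise_sd^2)`; after the plateau the curve
#' stays at the plateau level `a * plateau^b` with (typically larger)
#' lognormal noise of SD `late_noise_sd`.  Draws come from the current
#' global RNG unless `seed` is given.
#'
#' @param a Initial latency scale in seconds (> 0).
#' @param b Learning exponent (dimensionless; negative values learn).
#' @param plateau Trial index of plateau onset; `plateau >= n_trials`
#'   disables the late phase.
#' @param noise_sd,late_noise_sd Non-negative log-latency noise SDs.
#' @param n_trials Number of trials (>= 4).
#' @param t_max Latency ceiling in seconds.
#' @param seed Optional integer seed (global RNG state preserved).
#'
#' @return Numeric vector of `n_trials` latencies in `(0, t_max]`.
#' @export
simulate_latency_series <- function(a, b, plateau, noise_sd = 0.06,
                                    late_noise_sd = 0.45, n_trials = 20L,
                                    t_max = 60, seed = NULL) {
  check_number(a, "a")
  stop_if(a <= 0, "`a` must be positive")
  check_number(b, "b")
  check_count(n_trials, "n_trials", lower = 4L)
  check_count(plateau, "plateau")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(late_noise_sd, "late_noise_sd", lower = 0)
  check_number(t_max, "t_max")
  stop_if(t_max <= 0, "`t_max` must be positive")

  x <- seq_len(n_trials)
  mu <- a * pmin(x, plateau)^b
  sds <- ifelse(x <= plateau, noise_sd, late_noise_sd)
  eps <- with_seed(seed, stats::rnorm(n_trials, 0, sds))
  pmin(t_max, mu * exp(eps))
}

# trend-free i.i.d. latencies for a planted non-learner
nonlearner_series <- function(n_trials, t_max, level_sd = 0.45) {
  pmin(t_max, 0.6 * t_max * exp(stats::rnorm(n_trials, 0, level_sd)))
}

# Gaussian mixing given a matrix Z of iid standard normals (n x 7):
# fornix MD shares weight target_r with the standardised true b; FA tracks
# MD within tract at `fa_md_coupling`; ILF, volumes and gender are
# independent of b.
mix_metrics <- function(true_b, Z, params) {
  bstar <- (true_b - mean(true_b)) / stats::sd(true_b)
  mix <- function(target, z) target * bstar + sqrt(1 - target^2) * z
  cpl <- params$fa_md_coupling

  fornix_md_z <- mix(params$target_r_fornix_md, Z[, 1])
  fornix_fa_z <- cpl * fornix_md_z + sqrt(1 - cpl^2) * Z[, 2]
  ilf_md_z <- mix(params$target_r_ilf_md, Z[, 3])
  ilf_fa_z <- cpl * ilf_md_z + sqrt(1 - cpl^2) * Z[, 4]
  etiv_z <- Z[, 5]
  vol_z <- 0.4 * etiv_z + sqrt(1 - 0.4^2) * Z[, 6]

  data.frame(
    fornix_md = pmax(0.05, 0.80 + 0.05 * fornix_md_z),   # 10^-3 mm^2/s
    fornix_fa = pmin(0.99, pmax(0.01, 0.45 + 0.04 * fornix_fa_z)),
    ilf_md = pmax(0.05, 0.78 + 0.04 * ilf_md_z),
    ilf_fa = pmin(0.99, pmax(0.01, 0.48 + 0.03 * ilf_fa_z)),
    hippocampal_volume = pmax(1000, 7800 + 600 * vol_z),  # mm^3, bilateral
    etiv = pmax(8e5, 1.5e6 + 1.2e5 * etiv_z),             # mm^3
    gender = as.integer(Z[, 7] >= stats::qnorm(params$p_female)))
}

#' Generate tract metrics correlated with the true learning rate
#'
#' Builds fornix and ILF diffusion metrics, hippocampal and intracranial
#' volumes, and a binary gender code for a vector of true learning
#' exponents.  Fornix MD is constructed as a Gaussian mixture of the
#' standardised `true_b` (weight `target_r_fornix_md`) and independent
#' noise, so its population correlation with `true_b` equals the target by
#' construction; ILF metrics, volumes and gender are generated
#' independently of `true_b` (ILF MD honouring `target_r_ilf_md`, default
#' 0).  Within each tract FA is negatively coupled to MD
#' (`fa_md_coupling`), which propagates the behavioural association to FA
#' with the predicted negative sign.
#'
#' @param true_b Numeric vector (length >= 3) of learning exponents with
#'   non-zero variance.
#' @param params A [cohort_params()] object (its `n_participants` is
#'   ignored here).
#' @param seed Optional integer seed (global RNG state preserved).
#'
#' @return A data frame with columns `fornix_md`, `fornix_fa`, `ilf_md`,
#'   `ilf_fa` (MD in 10^-3 mm^2/s, FA dimensionless), `hippocampal_volume`,
#'   `etiv` (mm^3), `gender` (0/1).
#' @export
induce_correlated_metrics <- function(true_b, params, seed = NULL) {
  stop_if(!inherits(params, "cohort_params"),
          "`params` must be a cohort_params object")
  stop_if(!is.numeric(true_b) || length(true_b) < 3L,
          "`true_b` must be numeric with length >= 3")
  stop_if(stats::sd(true_b) == 0, "`true_b` has zero variance")
  Z <- with_seed(seed,
                 matrix(stats::rnorm(length(true_b) * 7), ncol = 7))
  mix_metrics(true_b, Z, params)
}

# one truncated-negative normal draw by rejection
rtruncnorm_negative <- function(mean, sd) {
  repeat {
    v <- stats::rnorm(1, mean, sd)
    if (v < 0) return(v)
  }
}

#' Simulate a full synthetic cohort
#'
#' Draws per-participant ground truth (`a` uniform in `a_range`, `b`
#' normal truncated to negative values, plateau onset uniform in
#' `plateau_range`, non-learner flags with probability
#' `nonlearner_fraction`), generates latency series (trend-free i.i.d.
#' latencies for non-learners) and correlated tract metrics, and returns
#' everything alongside the lossless ground truth so recovery can be
#' scored.  Every participant consumes an independent RNG substream of the
#' master seed, so enlarging the cohort leaves earlier participants
#' unchanged.
#'
#' @param params A [cohort_params()] object.
#'
#' @return A list of class `nav_cohort`: `latencies` (wide data frame:
#'   `participant_id`, `trial_01`..), `metrics` (see
#'   [induce_correlated_metrics()], plus `participant_id`), `truth`
#'   (`participant_id`, `true_a`, `true_b`, `true_plateau`, `is_learner`),
#'   and `params`.
#' @export
simulate_cohort <- function(params) {
  stop_if(!inherits(params, "cohort_params"),
          "`params` must be a cohort_params object")
  n <- params$n_participants
  nt <- params$n_trials
  streams <- rng_streams(params$seed, n)

  true_a <- true_b <- numeric(n)
  plateau <- integer(n)
  learner <- logical(n)
  lat <- matrix(NA_real_, n, nt)
  Z <- matrix(NA_real_, n, 7)
  for (i in seq_len(n)) {
    with_rng_stream(streams[[i]], {
      learner[i] <- stats::runif(1) >= params$nonlearner_fraction
      true_a[i] <- stats::runif(1, params$a_range[1], params$a_range[2])
      true_b[i] <- rtruncnorm_negative(params$b_mean, params$b_sd)
      plateau[i] <- if (params$plateau_range[1] == params$plateau_range[2])
        params$plateau_range[1]
      else sample(params$plateau_range[1]:params$plateau_range[2], 1L)
      lat[i, ] <- if (learner[i])
        simulate_latency_series(true_a[i], true_b[i], plateau[i],
                                params$noise_sd, params$late_noise_sd,
                                nt, params$t_max)
      else nonlearner_series(nt, params$t_max)
      Z[i, ] <- stats::rnorm(7)
    })
  }

  ids <- sprintf("P%04d", seq_len(n))
  latencies <- data.frame(participant_id = ids, lat,
                          stringsAsFactors = FALSE)
  names(latencies) <- c("participant_id",
                        sprintf("trial_%02d", seq_len(nt)))
  metrics <- cbind(participant_id = ids, mix_metrics(true_b, Z, params))
  truth <- data.frame(participant_id = ids, true_a = true_a,
                      true_b = true_b, true_plateau = plateau,
                      is_learner = learner, stringsAsFactors = FALSE)
  structure(list(latencies = latencies, metrics = metrics, truth = truth,
                 params = params),
            class = "nav_cohort")
}

#' @export
print.nav_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic navigation cohort: %d participants x %d trials (%d planted non-learners, seed %d)\n",
    nrow(x$truth), x$params$n_trials, sum(!x$truth$is_learner),
    x$params$seed))
  invisible(x)
}

#' Simulate a navigating agent in the square arena
#'
#' A point agent takes fixed-length steps in an `arena_size` x `arena_size`
#' square containing a hidden axis-aligned square sensor.  Each step's
#' heading is, with probability `goal_bias`, the direct bearing to the
#' sensor centre and otherwise a uniformly random direction; walls reflect.
#' The trial ends on sensor entry or at the `t_max` timeout, and
#' `goal_bias` grows by `learning_increment` per completed trial (capped at
#' 1), emulating gradual place learning.  Start positions sit at the four
#' mid-walls and each block of four trials visits all four cardinal starts
#' in random order.
#'
#' @param goal_bias Initial probability of a goal-directed step, in [0, 1].
#' @param learning_increment Added to `goal_bias` after each trial.
#' @param n_trials Number of trials; default 20 (five blocks of four).
#' @param step_length Step length in virtual metres; default 0.25.
#' @param step_duration Step duration in seconds; default 0.1.
#' @param sensor_side Side of the square sensor in metres; default 0.8.
#' @param sensor_center Sensor centre coordinates; default `c(5.6, 5.6)`.
#' @param arena_size Side of the square arena in metres; default 8.
#' @param t_max Trial timeout in seconds; default 60.
#' @param seed Optional integer seed (global RNG state preserved).
#'
#' @return A list of class `arena_trajectories`: `trials` (data frame with
#'   `trial`, `start`, `latency`, `found`), `paths` (list of two-column
#'   position matrices, one row per step including the start), and the
#'   geometry parameters.
#' @export
simulate_arena_agent <- function(goal_bias, learning_increment = 0,
                                 n_trials = 20L, step_length = 0.25,
                                 step_duration = 0.1, sensor_side = 0.8,
                                 sensor_center = c(5.6, 5.6),
                                 arena_size = 8, t_max = 60, seed = NULL) {
  check_number(goal_bias, "goal_bias", lower = 0, upper = 1)
  check_number(learning_increment, "learning_increment", lower = 0)
  check_count(n_trials, "n_trials")
  check_number(step_length, "step_length")
  check_number(sensor_side, "sensor_side")
  stop_if(step_length <= 0 || step_duration <= 0 || sensor_side <= 0 ||
            arena_size <= 0 || t_max <= 0,
          "geometry and timing parameters must be positive")
  half <- sensor_side / 2
  stop_if(length(sensor_center) != 2L ||
            any(sensor_center - half < 0) ||
            any(sensor_center + half > arena_size),
          "sensor square must lie inside the arena")

  starts <- rbind(N = c(arena_size / 2, arena_size),
                  S = c(arena_size / 2, 0),
                  E = c(arena_size, arena_size / 2),
                  W = c(0, arena_size / 2))
  max_steps <- floor(t_max / step_duration)

  with_seed(seed, {
    n_blocks <- ceiling(n_trials / 4)
    order_lab <- unlist(lapply(seq_len(n_blocks), function(bk)
      rownames(starts)[sample.int(4)]))[seq_len(n_trials)]

    paths <- vector("list", n_trials)
    latency <- numeric(n_trials)
    found <- logical(n_trials)
    gb <- goal_bias
    for (tr in seq_len(n_trials)) {
      pos <- starts[order_lab[tr], ]
      path <- matrix(NA_real_, max_steps + 1L, 2L)
      path[1L, ] <- pos
      hit <- FALSE
      steps <- 0L
      while (steps < max_steps) {
        steps <- steps + 1L
        theta <- if (stats::runif(1) < gb)
          atan2(sensor_center[2] - pos[2], sensor_center[1] - pos[1])
        else stats::runif(1, 0, 2 * pi)
        pos <- pos + step_length * c(cos(theta), sin(theta))
        # reflecting walls
        pos <- ifelse(pos < 0, -pos, pos)
        pos <- ifelse(pos > arena_size, 2 * arena_size - pos, pos)
        path[steps + 1L, ] <- pos
        if (all(abs(pos - sensor_center) <= half)) {
          hit <- TRUE
          break
        }
      }
      paths[[tr]] <- path[seq_len(steps + 1L), , drop = FALSE]
      latency[tr] <- min(t_max, steps * step_duration)
      found[tr] <- hit
      gb <- min(1, gb + learning_increment)
    }
    structure(list(trials = data.frame(trial = seq_len(n_trials),
                                       start = order_lab,
                                       latency = latency, found = found,
                                       stringsAsFactors = FALSE),
                   paths = paths, step_length = step_length,
                   step_duration = step_duration,
                   sensor_side = sensor_side,
                   sensor_center = sensor_center,
                   arena_size = arena_size, t_max = t_max),
              class = "arena_trajectories")
  })
}

#' Flatten arena trajectories to a long data frame
#'
#' @param x An `arena_trajectories` object.
#' @param row.names,optional,... Ignored; present for method consistency.
#' @return Data frame with columns `trial`, `step`, `x`, `y`.
#' @export
as.data.frame.arena_trajectories <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  do.call(rbind, lapply(seq_along(x$paths), function(tr) {
    p <- x$paths[[tr]]
    data.frame(trial = tr, step = seq_len(nrow(p)) - 1L,
               x = p[, 1], y = p[, 2])
  }))
}
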