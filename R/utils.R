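# internal helpers: argument checks and reproducible RNG streams

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x) && allow_null) return(invisible(NULL))
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          sprintf("`%s` must be a single finite number", name))
  stop_if(x < lower || x > upper,
          sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  invisible(NULL)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  stop_if(x != as.integer(x), sprintf("`%s` must be an integer", name))
  invisible(NULL)
}

# validate one participant's latency series
check_series <- function(latencies, t_max, min_len = 4L) {
  stop_if(!is.numeric(latencies) || anyNA(latencies),
          "latencies must be numeric with no missing values")
  stop_if(length(latencies) < min_len,
          sprintf("latency series must contain at least %d trials, got %d",
                  min_len, length(latencies)))
  stop_if(any(latencies <= 0) || any(latencies > t_max),
          sprintf("all latencies must lie in (0, %s]", t_max))
  invisible(NULL)
}

# Evaluate `expr` without disturbing the caller's RNG state (including the
# generator kind, which .Random.seed encodes).
with_preserved_rng <- function(expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)   # force RNG initialisation so state can be restored
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  expr
}

# Deterministic per-participant RNG substreams (L'Ecuyer-CMRG).  Stream i
# depends only on (seed, i), so enlarging a cohort never perturbs the draws
# of earlier participants.
rng_streams <- function(seed, n) {
  check_count(seed, "seed", lower = 0L)
  check_count(n, "n")
  with_preserved_rng({
    suppressWarnings(set.seed(seed, kind = "L'Ecuyer-CMRG"))
    s <- get(".Random.seed", envir = globalenv())
    streams <- vector("list", n)
    for (i in seq_len(n)) {
      s <- parallel::nextRNGStream(s)
      streams[[i]] <- s
    }
    streams
  })
}

# Run `expr` with the RNG positioned at `stream`, restoring state afterwards.
with_rng_stream <- function(stream, expr) {
  with_preserved_rng({
    assign(".Random.seed", stream, envir = globalenv())
    expr
  })
}

# Seed the global RNG for the duration of `expr` only (no-op when seed NULL).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  with_preserved_rng({
    set.seed(seed)
    expr
  })
}
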