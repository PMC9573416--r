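# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. With seed = NULL the expression runs on the
# ambient RNG stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Draw one normal deviate truncated to [lo, hi] by rejection; falls back to
# clamping after `max_tries` (only reachable for pathological bounds).
rtnorm1 <- function(mean, sd, lo = -Inf, hi = Inf, max_tries = 1000L) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in seq_len(max_tries)) {
    x <- rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lo), format(hi)), call. = FALSE)
  invisible(x)
}
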