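# Internal helpers shared across modules.

# Deterministic substream seeding: every simulator stage draws from its own
# named stream derived from the master seed, so adding or reordering a stage
# never perturbs the draws of earlier stages. Result stays below 2^31.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 2048L
  (as.integer(seed) %% 1000003L) * 2048L + as.integer(h)
}

with_substream <- function(seed, name, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

# row-wise ranking (midranks for ties); returns matrix of same shape
rank_rows <- function(x) {
  t(apply(x, 1L, rank))
}

# clamp correlations strictly inside (-1, 1) so Fisher Z stays finite
clamp_r <- function(r, eps = 1e-12) {
  pmin(pmax(r, -1 + eps), 1 - eps)
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
}

stop_if_not_fraction <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
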