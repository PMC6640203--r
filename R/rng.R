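# Per-particle random substreams.
#
# One root seed spawns one independent L'Ecuyer-CMRG substream per particle,
# so the random numbers a particle consumes depend only on (seed, particle id)
# and never on population size, evaluation order, or worker count.  All
# randomness is drawn in the coordinator before jobs are dispatched; energy
# workers are pure functions of their inputs.

# Spawn `n` independent RNG substreams from a root seed.  The global RNG
# state and kind are restored on exit.
make_rng_streams <- function(seed, n) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  suppressWarnings(set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG"))
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    streams[[i]] <- s
  }
  streams
}

# Evaluate `fn` (which may call runif/rnorm/...) with the RNG positioned at
# `state`; returns list(value, state) where `state` is the advanced stream.
# The ambient global RNG state is untouched.
stream_eval <- function(state, fn) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  assign(".Random.seed", state, envir = globalenv())
  value <- fn()
  new_state <- get(".Random.seed", envir = globalenv())
  if (had_seed) assign(".Random.seed", old, envir = globalenv())
  else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  list(value = value, state = new_state)
}

# Run `expr` under a local seed; the ambient RNG state is restored on exit.
# Used by the single-walker searchers (SA, BH) and the oracle.
with_seed_local <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  expr
}
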