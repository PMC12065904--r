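## Internal helpers.

## Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  state <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", state, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## rolling mean of k adjacent samples (k = 2 gives 2-point smoothing)
roll_mean <- function(x, k = 2) {
  if (k <= 1 || length(x) < k) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 1)[k:length(x)])
}
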