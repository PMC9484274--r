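# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-stage seeds fanned out from one master seed, kept inside
# the 32-bit integer range.
deriveSeeds <- function(seed) {
  seed <- as.integer(seed)
  m <- 2147483647
  list(generator  = seed %% m,
       fit        = (seed + 1000003L) %% m,
       split      = (seed + 2000003L) %% m,
       classifier = (seed + 3000003L) %% m)
}
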