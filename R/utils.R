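# evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so package functions never perturb the user's stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# fixed per-stage offsets from the pipeline's global seed, so any stage can
# be re-run in isolation with the same stream it saw inside the pipeline
.stageSeed <- function(seed, stage) {
  offs <- c(som = 101L, autocm = 211L, synthetic = 307L, mds = 401L)
  as.integer((as.integer(seed) + offs[[stage]]) %% .Machine$integer.max)
}
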