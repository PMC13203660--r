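#' @include AllClasses.R
NULL

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
# All stochastic operations in the package route through this, which is what
# makes every generator bit-reproducible for a fixed seed.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Fan a global seed out to per-stage seeds by fixed offsets, so a stage rerun
# in isolation reproduces its in-pipeline draws. Kept below 2^31 - 1.
stageSeed <- function(seed, stage) {
  offs <- c(simulate = 101L, occurrences = 211L, thin = 307L,
            screen = 401L, pabs = 503L, cv = 601L, classify = 701L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 1009 + offs[[stage]]) %% 2147483647)
}
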