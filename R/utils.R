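# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic sub-stream seeds below 2^31, so e.g. the genotype and
# phenotype generators draw from independent streams of one master seed.
derive_seed <- function(seed, k) {
  ((as.numeric(seed) %% 2147483647) * 48271 + 11 * k) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
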