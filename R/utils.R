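# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring (or removing) the
# caller's RNG state afterwards, so library calls never disturb user
# reproducibility.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a distinct 32-bit sub-seed from a base seed and a stream label.
sub_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(stream) * 7L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
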