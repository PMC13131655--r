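# Run code with a locally set RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package is funnelled through this so a
# single integer seed makes a whole analysis reproducible.
local_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) abort("a seed is required")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive an independent child seed from a root seed so that adding one
# generator never perturbs the draws of another. Kept below 2^31 - 1.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1009) %% 2147483647L)
}

`%||%` <- rlang::`%||%`
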