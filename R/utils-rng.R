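# local, restorable RNG handling so every generator is a pure function of
# its arguments (including seed) and never disturbs the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# evaluate expr under set.seed(seed), restoring the caller's RNG state after
.with_seed <- function(seed, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  expr
}

# derive a distinct sub-seed (kept below 2^31) from a base seed and a stage tag
.sub_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * k) %% 2147483647
}
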