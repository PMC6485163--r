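# Run code with a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the current RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a bounded child seed from a master seed and a stream index,
# keeping the result within the 32-bit integer range R requires.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 9973) %% 2147483629)
}
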