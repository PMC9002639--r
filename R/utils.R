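# Seed plumbing for the simulators.  Streams are derived hierarchically
# (study seed -> per-record seed) so a record's realization is stable when
# unrelated parts of a design change.  Arithmetic stays below 2^53 so the
# derivation is exact in doubles, and results stay below 2^31 - 1.

.mix_seed <- function(seed, key) {
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer((as.double(seed) + h * 69069) %% 2147483647)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}
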