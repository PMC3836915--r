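# Internal helpers.

# Evaluate `code` under `set.seed(seed)` and restore the caller's RNG
# state afterwards, so seeded helpers never perturb the global stream.
with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic per-respondent substream seed, kept inside 32-bit range.
substream_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index) %% 2147483647)
}

profile_codes <- function(profiles) {
  vapply(profiles, function(p) p$code, character(1))
}
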