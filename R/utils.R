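# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stage sub-seed from a master seed; keeps the result a valid
# 32-bit integer seed. Stages draw from independent streams so that, e.g.,
# adding probes to the annotation stage does not perturb expression draws.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

# Floor intensities at a small positive epsilon before ratio arithmetic.
floor_eps <- function(x, epsilon) {
  stopifnot(is.numeric(epsilon), epsilon >= 0)
  pmax(x, epsilon)
}

# Full-precision numeric formatting for text round-trips.
fmt_num <- function(x) {
  ifelse(x == round(x) & abs(x) < 1e15, sprintf("%.0f", x), sprintf("%.17g", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
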