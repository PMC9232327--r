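# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state on
# exit. All generator entry points route their randomness through this so that
# identical configs give bit-identical outputs without disturbing user RNG.
local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-(subject, combo, stage) seed from a base seed. Kept well below
# 2^31 so set.seed() always receives a valid 32-bit integer.
derive_seed <- function(base_seed, subject_index, combo = 0L, stage = 0L) {
  b <- as.integer(abs(as.numeric(base_seed)) %% 1e6)
  b * 2000L + as.integer(subject_index) * 20L + as.integer(combo) * 5L +
    as.integer(stage)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
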