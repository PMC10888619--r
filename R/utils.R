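# Internal helpers shared across the package.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a master seed and an index, kept inside 32-bit
# integer range so it is always a legal `set.seed()` argument.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

# Nearest integer, ties rounded away from zero (the convention used when
# converting regression coefficients to risk points).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

expit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

`%||%` <- function(a, b) if (is.null(a)) b else a
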