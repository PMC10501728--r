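# Internal helpers: seed derivation, scoped RNG, logging.

# Deterministically derive a child seed from a master seed and one or more
# integer tags. Uses a Weyl-style mix kept in double precision; every
# intermediate stays below 2^53 so arithmetic is exact, and the result is a
# valid 32-bit seed.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  h <- (as.numeric(seed) %% 2147483647) + 1
  for (t in tags) {
    h <- (h * 48271 + (as.numeric(t) %% 2147483647) + 1) %% 2147483647
    h <- (h * 16807) %% 2147483647
  }
  as.integer(h)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

dsaf_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[dsafgs] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up, used for test-set sizing so the split rule is unambiguous
round_half_up <- function(x) floor(x + 0.5)
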