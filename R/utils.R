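# Seed plumbing and small helpers.

#' Derive a named RNG sub-stream seed
#'
#' All randomness in the package flows from one top-level seed; each
#' operation draws from its own sub-stream so that, e.g., re-rendering one
#' timepoint does not shift the draws of another. The sub-stream seed is a
#' deterministic 31-bit hash of the top-level seed and a label.
#'
#' @param seed top-level integer seed.
#' @param label character label of the sub-stream.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
deriveSeed <- function(seed, label) {
  h <- as.numeric(seed) %% 2147483647
  for (k in utf8ToInt(as.character(label)))
    h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

# Evaluate expr with a local RNG state seeded at `seed`, restoring the
# caller's state afterwards.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic fingerprint of a character vector (polynomial rolling hash,
# two co-prime moduli, 16 hex digits). Used only to fingerprint config files
# in run manifests; not cryptographic.
textFingerprint <- function(x) {
  s <- utf8ToInt(paste(x, collapse = "\n"))
  h1 <- 0; h2 <- 0
  for (k in s) {
    h1 <- (h1 * 131 + k) %% 2147483647
    h2 <- (h2 * 137 + k) %% 2147483629
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
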