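# internal helpers shared across modules

# Evaluate `expr` under a locally-seeded RNG, restoring the caller's RNG
# state afterwards. seed = NULL leaves the global RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a parent seed and a stage index, kept within the
# 32-bit integer range. Documented contract: child = (seed * 97 + index) mod
# (2^31 - 1), never 0.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  child <- (as.double(seed) * 97 + as.double(index)) %% 2147483647
  as.integer(max(1, child))
}

# Weight vector -> normalised cumulative probabilities for the C++ samplers.
cum_weights <- function(w, n) {
  if (is.null(w)) w <- rep(1, n)
  stopifnot(length(w) == n, all(w >= 0), any(w > 0))
  cumsum(w) / sum(w)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
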