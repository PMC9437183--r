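# Small internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible child seed from a master seed
#'
#' Counter-based splitting: each (master seed, index...) pair maps to a fixed
#' 31-bit integer, so population simulations can hand every fiber and every
#' repetition its own independent, reproducible stream without consuming the
#' global RNG state in an order-dependent way.
#'
#' @param master Integer master seed.
#' @param ... One or more non-negative integer indices (fiber, repetition, ...).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, 3)
#' derive_seed(42, 3, 7)
derive_seed <- function(master, ...) {
  idx <- c(...)
  stopifnot(length(idx) >= 1, all(idx >= 0))
  h <- as.numeric(master) %% 2147483647
  for (i in idx) {
    # 65539-free LCG-style fold; constants are odd primes well below 2^31
    h <- (h * 48271 + as.numeric(i) * 16807 + 12345) %% 2147483647
  }
  as.integer(h) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# dB conversions used throughout: levels are 20*log10 amplitude ratios.
db_to_ratio <- function(db) 10^(db / 20)
ratio_to_db <- function(r) 20 * log10(r)

# Reference sound pressure, Pa.
P_REF <- 20e-6
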