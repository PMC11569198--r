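# Internal helpers shared across modules.

#' @keywords internal
#' @import stats
#' @import utils
"_PACKAGE"

# 32-bit helpers on doubles (values in [0, 2^32)); R's bitwXor only
# covers 31-bit signed ints, so XOR is done on 16-bit halves and modular
# multiplication by split products.
xor32 <- function(a, b) {
  bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
}
mulmod32 <- function(a, b) {
  lo <- a %% 65536
  hi <- a %/% 65536
  (lo * b + ((hi * b) %% 65536) * 65536) %% 4294967296
}
# murmur3 finalizer: full avalanche, so related purposes map to
# unrelated seeds
fmix32 <- function(x) {
  x <- xor32(x, x %/% 65536)
  x <- mulmod32(x, 2246822507)
  x <- xor32(x, x %/% 8192)
  x <- mulmod32(x, 3266489909)
  xor32(x, x %/% 65536)
}

# Deterministic sub-seed: every stochastic operation draws from its own
# stream so that identical (config, seed) reproduce identical output
# regardless of call order.  The avalanche mixing keeps streams for
# related purposes (e.g. consecutive replicates) far apart in seed
# space; the result stays strictly below 2^31 - 1.
seed_for <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- abs(seed) %% 4294967296
  for (ch in utf8ToInt(purpose)) {
    h <- fmix32(xor32(h, ch))
  }
  as.integer(fmix32(h) %% 2147483629)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_invalid <- function(...) {
  stop(structure(class = c("crossprs_invalid_config", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_structural <- function(...) {
  stop(structure(class = c("crossprs_structural_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
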