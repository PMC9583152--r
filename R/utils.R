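# Internal helpers: deterministic seed streams and local RNG scoping.

# Deterministic 31-bit sub-seed from a master seed and a string key.
# Polynomial string hash mixed with the master seed; per-(drug, channel) or
# per-repeat streams derived this way are independent of evaluation order.
derive_seed <- function(master, key) {
  stopifnot(length(master) == 1, is.finite(master))
  h <- as.double(master %% 2147483647)
  for (c in utf8ToInt(paste0("#", key))) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
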