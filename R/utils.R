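# Internal helpers shared across modules.

# Plug-in (maximum-likelihood) Shannon entropy in bits from a vector of
# counts or probabilities. Zero entries contribute nothing.
plugin_entropy <- function(x) {
  p <- x[x > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

# KL divergence in bits between two probability vectors on the same support.
# Terms with p = 0 contribute 0; q must be > 0 wherever p > 0.
kl_bits <- function(p, q) {
  stopifnot(length(p) == length(q))
  keep <- p > 0
  if (any(q[keep] <= 0)) {
    stop("KL divergence undefined: q has zero mass where p is positive")
  }
  sum(p[keep] * log2(p[keep] / q[keep]))
}

# All 2^K binary states as a (2^K x K) 0/1 matrix. Row r encodes the word
# integer r - 1 with unit i on bit i - 1 (catalog order, stable convention).
binary_states <- function(K) {
  stopifnot(K >= 1, K <= 24)
  n <- 2L^K
  m <- matrix(0L, n, K)
  for (i in seq_len(K)) {
    m[, i] <- bitwAnd(seq_len(n) - 1L, bitwShiftL(1L, i - 1L)) > 0L
  }
  storage.mode(m) <- "integer"
  m
}

# Encode raster columns (words) as integers in [0, 2^K - 1], bit i = unit i.
encode_words <- function(raster) {
  K <- nrow(raster)
  stopifnot(K <= 30)
  as.integer(crossprod(raster, 2^(seq_len(K) - 1))[, 1] %% 2^31)
}

# Run `expr` with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && x >= 1 && x == floor(x)
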