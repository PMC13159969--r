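#' Count entropy of a population raster
#'
#' Entropy (bits) of the distribution of the number of simultaneously
#' active units per bin, ignoring which units they are. For K units the
#' count takes at most `K + 1` values, so `0 <= H_count <= log2(K + 1)`.
#'
#' @param raster a `binarized_raster`.
#' @param correction `"none"` (plug-in, default) or `"miller_madow"`.
#' @return entropy in bits.
#' @export
count_entropy <- function(raster, correction = c("none", "miller_madow")) {
  correction <- match.arg(correction)
  counts <- tabulate(colSums(raster) + 1L, nrow(raster) + 1L)
  h <- plugin_entropy(counts)
  if (correction == "miller_madow") {
    h <- h + (sum(counts > 0) - 1) / (2 * ncol(raster) * log(2))
  }
  h
}

#' Word entropy of a population raster
#'
#' Entropy (bits) of the distribution of binary population words (the
#' pattern of which units are active in a bin, preserving identity). Since
#' the count is a function of the word, word entropy is always at least the
#' count entropy of the same raster; with K units there are `2^K` possible
#' words so `0 <= H_word <= K`.
#'
#' @inheritParams count_entropy
#' @return entropy in bits.
#' @export
word_entropy <- function(raster, correction = c("none", "miller_madow")) {
  correction <- match.arg(correction)
  counts <- table(encode_words(raster))
  h <- plugin_entropy(as.numeric(counts))
  if (correction == "miller_madow") {
    h <- h + (length(counts) - 1) / (2 * ncol(raster) * log(2))
  }
  h
}

#' Count and word entropy across subsampled population sizes
#'
#' Recordings yield different numbers of units, so entropies are compared
#' at matched population sizes by subsampling: for each K in `K_range`,
#' `n_subsamples` random K-unit subsets are drawn and the count and word
#' entropies of each sub-raster computed. Bootstrap resampling of time bins
#' (with replacement) provides a stability estimate (SD over
#' `n_bootstrap` resamples) for each subsample.
#'
#' @param raster a `binarized_raster`.
#' @param K_range population sizes to evaluate (default `2:18`); sizes
#'   exceeding the number of units are skipped with a warning.
#' @param n_subsamples random unit subsets per K (default 100).
#' @param n_bootstrap bootstrap resamples of time bins per subsample
#'   (default 100; 0 disables the spread estimate).
#' @param seed RNG seed.
#' @return data.frame in long format: `K`, `subsample`, `kind`
#'   (`"count"`/`"word"`), `entropy_bits`, `bootstrap_sd`.
#' @export
subsampled_entropy <- function(raster, K_range = 2:18, n_subsamples = 100,
                               n_bootstrap = 100, seed = 1) {
  n_units <- nrow(raster)
  n_bins <- ncol(raster)
  usable <- K_range[K_range <= n_units]
  if (length(usable) < length(K_range)) {
    warning("skipping K > ", n_units, " (only ", n_units, " units available)")
  }
  with_seed(seed, {
    rows <- list()
    for (K in usable) {
      for (s in seq_len(n_subsamples)) {
        idx <- sample.int(n_units, K)
        sub <- raster[idx, ]
        hc <- count_entropy(sub)
        hw <- word_entropy(sub)
        sd_c <- sd_w <- NA_real_
        if (n_bootstrap > 0) {
          boot <- vapply(seq_len(n_bootstrap), function(b) {
            bins <- sample.int(n_bins, n_bins, replace = TRUE)
            bsub <- sub[, bins]
            c(count_entropy(bsub), word_entropy(bsub))
          }, numeric(2))
          sd_c <- stats::sd(boot[1, ])
          sd_w <- stats::sd(boot[2, ])
        }
        rows[[length(rows) + 1]] <- data.frame(
          K = K, subsample = s,
          kind = c("count", "word"),
          entropy_bits = c(hc, hw),
          bootstrap_sd = c(sd_c, sd_w))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
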