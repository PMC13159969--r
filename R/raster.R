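#' Binarized population raster
#'
#' Discretizes a set of spike trains into a binary units-by-bins matrix.
#' Time is partitioned into half-open bins `[t, t + bin)` aligned to the
#' recording start; a bin is set to 1 if the unit fired at least once within
#' it, irrespective of how many spikes fell in the bin. The fraction of
#' occupied bins holding more than one spike is recorded in the
#' `multi_spike_fraction` attribute so the validity of the single-spike-per-bin
#' approximation can be audited per recording.
#'
#' @param trains list of numeric vectors of spike times in seconds (one per
#'   unit), each sorted increasing, all within `[0, duration_s)`.
#' @param duration_s recording duration in seconds.
#' @param bin_ms bin width in milliseconds (default 10).
#' @return an integer matrix of class `binarized_raster`, units x bins, with
#'   attributes `bin_s`, `duration_s`, `unit_ids` and `multi_spike_fraction`.
#' @examples
#' r <- binarize(list(u1 = c(0.005, 0.007, 0.5)), duration_s = 1)
#' sum(r)            # two occupied bins: 5 and 7 ms collapse into one
#' @export
binarize <- function(trains, duration_s, bin_ms = 10) {
  stopifnot(is.list(trains), duration_s > 0, bin_ms > 0)
  bin_s <- bin_ms / 1000
  n_bins <- floor(duration_s / bin_s + 1e-9)
  K <- length(trains)
  mat <- matrix(0L, K, n_bins)
  n_occupied <- 0L
  n_multi <- 0L
  for (i in seq_len(K)) {
    t <- trains[[i]]
    if (length(t) == 0) next
    if (any(t < 0) || any(t >= duration_s)) {
      stop("spike times must lie in [0, duration_s) for unit ", i)
    }
    idx <- floor(t / bin_s) + 1L
    idx <- idx[idx <= n_bins]
    counts <- tabulate(idx, n_bins)
    mat[i, counts > 0L] <- 1L
    n_occupied <- n_occupied + sum(counts > 0L)
    n_multi <- n_multi + sum(counts > 1L)
  }
  ids <- names(trains)
  if (is.null(ids)) ids <- paste0("u", seq_len(K))
  new_raster(mat, bin_s,
             unit_ids = ids,
             multi_spike_fraction = if (n_occupied > 0) n_multi / n_occupied else 0)
}

new_raster <- function(mat, bin_s, unit_ids = NULL, multi_spike_fraction = NULL) {
  stopifnot(is.matrix(mat), all(mat %in% c(0L, 1L)))
  storage.mode(mat) <- "integer"
  structure(mat,
            bin_s = bin_s,
            duration_s = ncol(mat) * bin_s,
            unit_ids = unit_ids %||% paste0("u", seq_len(nrow(mat))),
            multi_spike_fraction = multi_spike_fraction,
            class = c("binarized_raster", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.binarized_raster <- function(x, ...) {
  cat(sprintf("binarized raster: %d units x %d bins (%.0f ms bins, %.1f s)\n",
              nrow(x), ncol(x), attr(x, "bin_s") * 1000, attr(x, "duration_s")))
  cat(sprintf("  mean occupancy per unit-bin: %.4f\n", mean(x)))
  invisible(x)
}

# subsetting follows matrix semantics (single rows/columns drop to vectors)
# but keeps the raster class and metadata whenever the result is a matrix
#' @export
`[.binarized_raster` <- function(x, i, j, ..., drop = TRUE) {
  m <- x
  class(m) <- NULL
  out <- if (missing(i) && missing(j)) m
         else if (missing(i)) m[, j, drop = drop]
         else if (missing(j)) m[i, , drop = drop]
         else m[i, j, drop = drop]
  if (is.matrix(out)) {
    ids <- attr(x, "unit_ids")
    if (!missing(i)) ids <- ids[i]
    attributes(out) <- list(dim = dim(out))
    new_raster(out, attr(x, "bin_s"), unit_ids = ids,
               multi_spike_fraction = attr(x, "multi_spike_fraction"))
  } else {
    as.vector(out)
  }
}
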