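#' Gaussian smoothing of a binarized spike train
#'
#' Convolves a binarized train with a unit-area Gaussian kernel
#' (`sigma_ms`, default 25 ms) on the raster grid. The kernel is truncated
#' at +/- 4 sigma and normalized to sum to one, so the smoothed series
#' conserves total spike mass.
#'
#' @param train binary (or count) vector on the raster grid.
#' @param bin_ms raster bin width in ms (default 10).
#' @param sigma_ms Gaussian SD in ms (default 25).
#' @return numeric vector, same length as `train`.
#' @export
smooth_train <- function(train, bin_ms = 10, sigma_ms = 25) {
  sigma_bins <- sigma_ms / bin_ms
  half <- ceiling(4 * sigma_bins)
  kernel <- stats::dnorm(seq(-half, half), sd = sigma_bins)
  kernel <- kernel / sum(kernel)
  n <- length(train)
  padded <- c(rep(0, half), train, rep(0, half))
  out <- stats::filter(padded, kernel, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' Pairwise correlation matrix of smoothed spike trains
#'
#' Smooths every unit's binarized train with a Gaussian kernel
#' ([smooth_train()]) and computes the Pearson correlation coefficient for
#' all unit pairs. Zero-variance units (no spikes) yield `NA` entries and a
#' warning rather than a silent zero.
#'
#' @param raster a `binarized_raster` (units x bins).
#' @param sigma_ms Gaussian smoothing SD in ms (default 25).
#' @return matrix of class `correlation_matrix`: symmetric, unit diagonal,
#'   with attribute `sigma_ms`.
#' @export
pairwise_correlation <- function(raster, sigma_ms = 25) {
  stopifnot(nrow(raster) >= 2)
  bin_ms <- attr(raster, "bin_s") * 1000
  smoothed <- t(apply(raster, 1, smooth_train, bin_ms = bin_ms,
                      sigma_ms = sigma_ms))
  zero_var <- apply(smoothed, 1, stats::sd) == 0
  if (any(zero_var)) {
    warning("zero-variance unit(s) ",
            paste(which(zero_var), collapse = ", "),
            ": correlation undefined (NA)")
  }
  cm <- suppressWarnings(stats::cor(t(smoothed)))
  diag(cm) <- 1
  dimnames(cm) <- list(attr(raster, "unit_ids"), attr(raster, "unit_ids"))
  structure(cm, sigma_ms = sigma_ms,
            class = c("correlation_matrix", "matrix", "array"))
}

#' Upper triangle of a correlation matrix in long format
#'
#' @param cm a `correlation_matrix`.
#' @return data.frame `unit_i`, `unit_j`, `r`.
#' @export
correlation_pairs <- function(cm) {
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  data.frame(unit_i = ut[, 1], unit_j = ut[, 2], r = cm[ut])
}
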