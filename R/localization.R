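#' Triangulate a unit's position from multi-channel waveforms
#'
#' Estimates the soma position as the weighted mean of the channel
#' coordinates, each channel weighted by the integral of the absolute value
#' of the unit's mean waveform on that channel. A unit seen on only one
#' channel localizes exactly to that channel; a unit seen equally on two
#' channels localizes to their midpoint.
#'
#' @param mean_waveforms channels x window matrix of the unit's mean
#'   waveform per channel (uV).
#' @param channel_coords data.frame with `x_um`, `y_um` rows matching the
#'   waveform rows.
#' @return list `x_um`, `y_um`, `weights` (normalized per-channel weights).
#' @export
triangulate_position <- function(mean_waveforms, channel_coords) {
  if (!is.matrix(mean_waveforms)) mean_waveforms <- matrix(mean_waveforms, nrow = 1)
  stopifnot(nrow(mean_waveforms) == nrow(channel_coords))
  w <- rowSums(abs(mean_waveforms))
  if (sum(w) == 0) stop("all-zero waveforms: position undefined")
  w <- w / sum(w)
  list(x_um = sum(w * channel_coords$x_um),
       y_um = sum(w * channel_coords$y_um),
       weights = w)
}

#' Positions of all units in a catalog
#'
#' @param catalog a `unit_catalog` from [sort_spikes()].
#' @return data.frame `unit_id`, `x_um`, `y_um`.
#' @export
localize_units <- function(catalog) {
  pos <- lapply(catalog$units, function(u) {
    triangulate_position(u$mean_waveforms, catalog$channel_coords)
  })
  data.frame(unit_id = seq_along(pos),
             x_um = vapply(pos, `[[`, 0, "x_um"),
             y_um = vapply(pos, `[[`, 0, "y_um"))
}

#' Positional entropy of unit locations
#'
#' Quantifies how homogeneously units are spread over the recording area:
#' the area is tiled with square regions of side `region_size_um`, the
#' fraction of units in each region is taken as a probability distribution,
#' and its Shannon entropy `H = -sum p log2 p` is normalized by the entropy
#' of the spatially most random arrangement, `H_max = log2(min(n_units,
#' n_regions))` (with fewer units than regions, no arrangement can occupy
#' more than one region per unit). `H_norm = 0` means all units share one
#' region; `H_norm = 1` means maximal spread.
#'
#' Regions are half-open `[x, x + size)`, anchored at `origin_um`, so a
#' rigid translation of all positions by a multiple of the region size
#' leaves the result unchanged.
#'
#' @param positions data.frame with `x_um`, `y_um` (one row per unit).
#' @param region_size_um side of the square regions (um).
#' @param extent_um side of the (square) recording area (default 2100, the
#'   2.1 x 2.1 mm array field).
#' @param origin_um lower-left corner of the region grid (default `c(0, 0)`).
#' @return list of class `positional_entropy`: `region_size_um`, `H_bits`,
#'   `H_norm`, `n_regions`, `n_units`.
#' @export
positional_entropy <- function(positions, region_size_um, extent_um = 2100,
                               origin_um = c(0, 0)) {
  stopifnot(nrow(positions) >= 1, region_size_um > 0)
  n_side <- max(1L, ceiling(extent_um / region_size_um - 1e-9))
  ix <- pmin(pmax(floor((positions$x_um - origin_um[1]) / region_size_um), 0),
             n_side - 1)
  iy <- pmin(pmax(floor((positions$y_um - origin_um[2]) / region_size_um), 0),
             n_side - 1)
  region <- ix * n_side + iy
  counts <- table(region)
  H <- plugin_entropy(as.numeric(counts))
  n_regions <- n_side^2
  H_max <- log2(min(nrow(positions), n_regions))
  structure(list(region_size_um = region_size_um,
                 H_bits = H,
                 H_norm = if (H_max > 0) H / H_max else 0,
                 n_regions = n_regions,
                 n_units = nrow(positions)),
            class = "positional_entropy")
}

#' @export
print.positional_entropy <- function(x, ...) {
  cat(sprintf("positional entropy at %g um: H = %.3f bits, H_norm = %.3f (%d units, %d regions)\n",
              x$region_size_um, x$H_bits, x$H_norm, x$n_units, x$n_regions))
  invisible(x)
}

#' Positional-entropy sweep over length scales
#'
#' Evaluates [positional_entropy()] over a range of region sizes spanning
#' two log orders (default 100 um to 1 mm, ten logarithmic steps).
#'
#' @inheritParams positional_entropy
#' @param region_sizes_um region sizes to evaluate (um).
#' @return data.frame with one row per scale: `region_size_um`, `H_bits`,
#'   `H_norm`, `n_regions`, `n_units`.
#' @export
positional_entropy_sweep <- function(positions,
                                     region_sizes_um = 10^seq(2, 3, length.out = 10),
                                     extent_um = 2100, origin_um = c(0, 0)) {
  rows <- lapply(region_sizes_um, function(s) {
    as.data.frame(unclass(positional_entropy(positions, s, extent_um, origin_um)))
  })
  do.call(rbind, rows)
}
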