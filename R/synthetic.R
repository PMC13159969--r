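#' Exact sampler for the pairwise Ising model
#'
#' Draws i.i.d. population words from the Boltzmann distribution
#' `P(s) ~ exp(h.s + s'Js/2)` by full enumeration of the `2^K` states. Used
#' as ground truth for the maximum-entropy fitter: the sampled raster has
#' exactly the word distribution of [model_word_distribution()] in the large
#' sample limit.
#'
#' @param params an [ising_params()] object with `K <= 16`.
#' @param n_samples number of time bins to draw.
#' @param seed integer RNG seed (required: the sampler is deterministic
#'   given `(params, seed)`).
#' @param bin_s nominal bin width in seconds carried by the returned raster
#'   (default 0.01).
#' @return a `binarized_raster` (K x n_samples).
#' @export
sample_ising <- function(params, n_samples, seed, bin_s = 0.01) {
  stopifnot(inherits(params, "ising_params"), is_count(n_samples))
  if (params$K > 16) {
    stop("exact sampling limited to K <= 16 (2^K state enumeration); got K = ",
         params$K)
  }
  p <- model_word_distribution(params)
  words <- with_seed(seed, sample.int(length(p), n_samples, replace = TRUE, prob = p)) - 1L
  S <- binary_states(params$K)
  new_raster(t(S[words + 1L, , drop = FALSE]), bin_s)
}

# analytic latent threshold for a dichotomized Gaussian with target per-bin
# spike probability p: unit fires when its standard-normal latent exceeds z
dg_threshold <- function(p) stats::qnorm(1 - p)

#' Correlated spike trains via the dichotomized Gaussian
#'
#' Generates binary spike trains with target per-unit firing rates and a
#' target latent correlation structure by thresholding correlated standard
#' Gaussians: in every bin a latent vector `X ~ N(0, latent_corr)` is drawn
#' and unit `i` fires iff `X_i > qnorm(1 - rate_i * bin_s)`. Firing
#' probabilities match the requested rates exactly in expectation, and the
#' observed binary correlation is a monotone function of the latent one with
#' a closed form given by the bivariate-normal orthant probability.
#'
#' Continuous spike times are produced by jittering each occupied bin
#' uniformly within the bin, so binarizing at `bin_s` recovers the generated
#' raster exactly.
#'
#' @param rates_hz numeric vector of per-unit firing rates (Hz), all `>= 0`
#'   and with `rate * bin_s < 1`.
#' @param latent_corr latent correlation matrix (symmetric, unit diagonal,
#'   positive semidefinite). Scalar shorthand: a single number is used as
#'   the common off-diagonal correlation.
#' @param duration_s duration of the generated recording (seconds).
#' @param bin_s bin width in seconds (default 0.01, i.e. 10 ms).
#' @param seed integer RNG seed.
#' @return object of class `spike_trains`: list with `trains` (per-unit
#'   sorted spike times in seconds), `duration_s`, `raster`
#'   (`binarized_raster`), `rates_hz`, `latent_corr`.
#' @export
generate_correlated_trains <- function(rates_hz, latent_corr, duration_s,
                                       bin_s = 0.01, seed = 1) {
  K <- length(rates_hz)
  stopifnot(K >= 1, duration_s > 0, bin_s > 0)
  if (any(rates_hz < 0)) stop("rates must be non-negative")
  p <- rates_hz * bin_s
  if (any(p >= 1)) {
    stop("infeasible rate: rate * bin_s must be < 1 (got max ", max(p), ")")
  }
  if (length(latent_corr) == 1) {
    r <- latent_corr
    latent_corr <- matrix(r, K, K); diag(latent_corr) <- 1
  }
  latent_corr <- as.matrix(latent_corr)
  if (!all(dim(latent_corr) == K)) stop("latent_corr must be K x K")
  if (!isTRUE(all.equal(latent_corr, t(latent_corr), tolerance = 1e-8)) ||
      any(abs(diag(latent_corr) - 1) > 1e-8)) {
    stop("latent_corr must be symmetric with unit diagonal")
  }
  ev <- eigen(latent_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("latent_corr must be positive semidefinite")

  n_bins <- floor(duration_s / bin_s + 1e-9)
  z <- dg_threshold(p)
  raster <- with_seed(seed, {
    X <- MASS::mvrnorm(n_bins, mu = rep(0, K), Sigma = latent_corr)
    X <- matrix(X, n_bins, K)
    raster <- t(X > rep(z, each = n_bins)) * 1L
    # uniform jitter inside each occupied bin -> continuous, recoverable times
    attr(raster, "jitter") <- matrix(stats::runif(length(raster)), K, n_bins)
    raster
  })
  jit <- attr(raster, "jitter"); attr(raster, "jitter") <- NULL
  trains <- lapply(seq_len(K), function(i) {
    bins <- which(raster[i, ] == 1L)
    sort((bins - 1L + jit[i, bins]) * bin_s)
  })
  names(trains) <- paste0("u", seq_len(K))
  structure(list(trains = trains,
                 duration_s = n_bins * bin_s,
                 raster = new_raster(raster, bin_s),
                 rates_hz = rates_hz,
                 latent_corr = latent_corr),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("spike trains: %d units over %.1f s\n",
              length(x$trains), x$duration_s))
  cat("  rates (Hz):", format(round(vapply(x$trains, length, 0L) / x$duration_s, 2)), "\n")
  invisible(x)
}

#' Electrode grid geometry
#'
#' Coordinates of the recording electrodes: an `n_side x n_side` square grid
#' with the given pitch (defaults: 8 x 8 at 300 um, recording area
#' 2.1 x 2.1 mm).
#'
#' @param n_side electrodes per side (default 8).
#' @param pitch_um center-to-center spacing in micrometers (default 300).
#' @return data.frame with columns `channel`, `x_um`, `y_um`.
#' @export
mea_grid <- function(n_side = 8, pitch_um = 300) {
  g <- expand.grid(x_um = (seq_len(n_side) - 1) * pitch_um,
                   y_um = (seq_len(n_side) - 1) * pitch_um)
  data.frame(channel = seq_len(nrow(g)), g)
}

#' Canonical extracellular spike waveform template
#'
#' A single-trough biphasic template: a sharp negative deflection followed
#' by a slower positive overshoot and recovery, the stereotyped shape of an
#' extracellular action potential near a soma. The waveform window is 1 ms
#' before the trough and ~2 ms after (13 + 25 samples at 12.5 kHz). The
#' pronounced asymmetry distinguishes it from symmetric periodic noise,
#' which the sorter's symmetric-noise rejection removes.
#'
#' @param peak_uV trough amplitude in microvolts (positive number; the
#'   template reaches `-peak_uV`).
#' @param sr_hz sampling rate (default 12500).
#' @param n_pre,n_post samples before / after the trough (defaults 13, 24).
#' @param recovery_frac amplitude of the positive overshoot relative to the
#'   trough (default 0.35).
#' @return numeric vector of length `n_pre + n_post + 1` (uV), trough at
#'   index `n_pre + 1`.
#' @export
spike_template <- function(peak_uV = 80, sr_hz = 12500,
                           n_pre = 13, n_post = 24, recovery_frac = 0.35) {
  stopifnot(peak_uV > 0)
  t <- (seq_len(n_pre + n_post + 1) - (n_pre + 1)) / sr_hz * 1000  # ms
  w <- -exp(-(t / 0.25)^2) + recovery_frac * exp(-((t - 0.7) / 0.45)^2)
  w <- w - w[1]                      # start at baseline
  w <- w / abs(min(w)) * peak_uV     # trough exactly at -peak_uV
  w
}

#' Bundle planted ground truth for voltage synthesis
#'
#' @param trains list of per-unit sorted spike-time vectors (seconds).
#' @param positions_um data.frame or matrix with columns `x_um`, `y_um`, one
#'   row per unit, inside the recording extent.
#' @param duration_s recording duration.
#' @param ising_params optional true [ising_params()] behind the trains.
#' @param latent_corr optional latent correlation matrix behind the trains.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(trains, positions_um, duration_s,
                         ising_params = NULL, latent_corr = NULL) {
  positions_um <- as.data.frame(positions_um)
  stopifnot(length(trains) == nrow(positions_um),
            all(c("x_um", "y_um") %in% names(positions_um)))
  for (i in seq_along(trains)) {
    t <- trains[[i]]
    if (is.unsorted(t, strictly = TRUE)) {
      stop("spike times must be strictly increasing (unit ", i, ")")
    }
    if (length(t) && (min(t) < 0 || max(t) >= duration_s)) {
      stop("spike times outside [0, duration) for unit ", i)
    }
  }
  structure(list(unit_ids = names(trains) %||% paste0("u", seq_along(trains)),
                 trains = trains, positions_um = positions_um,
                 duration_s = duration_s,
                 ising_params = ising_params, latent_corr = latent_corr),
            class = "ground_truth")
}

#' Synthesize raw extracellular voltage from planted units
#'
#' Builds a multichannel voltage recording by placing each unit's waveform
#' template at its spike times on every channel, scaled by the distance
#' decay `1 / (1 + d / lambda_um)` from the unit's true position, plus
#' additive white Gaussian noise. Neighboring channels therefore see decayed
#' copies of each unit, which is what makes triangulation and cross-channel
#' deduplication testable.
#'
#' @param truth a [ground_truth()] object.
#' @param templates list of template vectors (one per unit), e.g. from
#'   [spike_template()]; a single vector is recycled.
#' @param grid channel coordinates from [mea_grid()] (or a subset of it).
#' @param noise_sd_uV standard deviation of the additive Gaussian noise.
#' @param sr_hz sampling rate (default 12500).
#' @param lambda_um spatial decay constant of template amplitude
#'   (default 150).
#' @param seed integer RNG seed.
#' @return object of class `voltage_recording`: `samples` (channels x
#'   samples matrix, uV), `sampling_rate_hz`, `channel_coords`, `duration_s`.
#' @export
synthesize_voltage <- function(truth, templates, grid, noise_sd_uV,
                               sr_hz = 12500, lambda_um = 150, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  n_units <- length(truth$trains)
  if (!is.list(templates)) templates <- rep(list(templates), n_units)
  stopifnot(length(templates) == n_units)
  for (tr in truth$trains) {
    if (anyDuplicated(tr)) stop("overlapping identical spike times on one unit")
  }
  n_ch <- nrow(grid)
  n_samples <- round(truth$duration_s * sr_hz)
  V <- with_seed(seed,
    matrix(stats::rnorm(n_ch * n_samples, sd = noise_sd_uV), n_ch, n_samples))
  for (u in seq_len(n_units)) {
    w <- templates[[u]]
    n_pre <- which.min(w) - 1L
    d <- sqrt((grid$x_um - truth$positions_um$x_um[u])^2 +
              (grid$y_um - truth$positions_um$y_um[u])^2)
    decay <- 1 / (1 + d / lambda_um)
    centers <- round(truth$trains[[u]] * sr_hz) + 1L
    for (s in centers) {
      i0 <- s - n_pre
      i1 <- i0 + length(w) - 1L
      if (i0 < 1L || i1 > n_samples) next
      V[, i0:i1] <- V[, i0:i1] + decay %o% w
    }
  }
  structure(list(samples = V, sampling_rate_hz = sr_hz,
                 channel_coords = grid, duration_s = n_samples / sr_hz),
            class = "voltage_recording")
}

#' @export
print.voltage_recording <- function(x, ...) {
  cat(sprintf("voltage recording: %d channels x %d samples (%.1f s at %.1f kHz)\n",
              nrow(x$samples), ncol(x$samples), x$duration_s,
              x$sampling_rate_hz / 1000))
  invisible(x)
}

#' Score a sorted catalog against planted ground truth
#'
#' Greedy one-to-one matching of recovered units to planted units by spike
#' coincidence: each recovered spike may claim at most one true spike within
#' `tol_ms`. Reports overall recall and precision plus the per-unit
#' assignment.
#'
#' @param catalog a `unit_catalog` from [sort_spikes()].
#' @param truth a [ground_truth()] object (or a plain list of true trains).
#' @param tol_ms matching tolerance in milliseconds (default 1).
#' @return list: `recall`, `precision`, `n_true_units`, `n_recovered_units`,
#'   `assignment` data.frame.
#' @export
score_sorting <- function(catalog, truth, tol_ms = 1) {
  true_trains <- if (inherits(truth, "ground_truth")) truth$trains else truth
  rec_trains <- lapply(catalog$units, `[[`, "spike_times_s")
  tol <- tol_ms / 1000
  match_count <- function(a, b) {
    # count of one-to-one matches within tol between two sorted time vectors
    i <- 1L; j <- 1L; m <- 0L
    while (i <= length(a) && j <= length(b)) {
      d <- a[i] - b[j]
      if (abs(d) <= tol) { m <- m + 1L; i <- i + 1L; j <- j + 1L }
      else if (d < 0) i <- i + 1L
      else j <- j + 1L
    }
    m
  }
  n_true <- length(true_trains); n_rec <- length(rec_trains)
  if (n_rec == 0) {
    return(list(recall = 0, precision = NA_real_, n_true_units = n_true,
                n_recovered_units = 0, assignment = NULL))
  }
  hits <- matrix(0L, n_true, n_rec)
  for (i in seq_len(n_true)) for (j in seq_len(n_rec)) {
    hits[i, j] <- match_count(true_trains[[i]], rec_trains[[j]])
  }
  # greedy one-to-one assignment by descending coincidence
  assign <- data.frame(true_unit = integer(), recovered_unit = integer(),
                       matched = integer())
  h <- hits
  repeat {
    m <- which.max(h)
    if (length(m) == 0 || h[m] == 0) break
    ij <- arrayInd(m, dim(h))
    assign <- rbind(assign, data.frame(true_unit = ij[1], recovered_unit = ij[2],
                                       matched = h[ij]))
    h[ij[1], ] <- 0L; h[, ij[2]] <- 0L
    if (nrow(assign) == min(n_true, n_rec)) break
  }
  matched <- sum(assign$matched)
  list(recall = matched / sum(lengths(true_trains)),
       precision = matched / sum(lengths(rec_trains)),
       n_true_units = n_true, n_recovered_units = n_rec,
       assignment = assign)
}
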