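#' Firing rates of the two halves of a recording
#'
#' Splits the recording at `T/2` and returns the firing rate on `[0, T/2)`
#' and `[T/2, T)`. A unit passes the half-split check when the two rates
#' agree within `tol_sd` Poisson standard errors of their difference:
#' under a homogeneous Poisson train each half-rate has variance
#' `rbar/(T/2)`, so `|r1 - r2| <= tol_sd * sqrt(2 * rbar / (T/2))`.
#'
#' @param spike_times_s sorted spike times (seconds).
#' @param duration_s recording duration (seconds).
#' @param tol_sd tolerance in Poisson SEs (default 3).
#' @return list `rate_first_hz`, `rate_second_hz`, `pass`.
#' @export
half_split_rates <- function(spike_times_s, duration_s, tol_sd = 3) {
  stopifnot(duration_s > 0)
  half <- duration_s / 2
  n1 <- sum(spike_times_s < half)
  n2 <- sum(spike_times_s >= half)
  r1 <- n1 / half
  r2 <- n2 / half
  if (n1 + n2 == 0) {
    warning("empty spike train: half-split check passes vacuously")
    return(list(rate_first_hz = 0, rate_second_hz = 0, pass = TRUE))
  }
  rbar <- (r1 + r2) / 2
  list(rate_first_hz = r1, rate_second_hz = r2,
       pass = abs(r1 - r2) <= tol_sd * sqrt(2 * rbar / half))
}

#' Moving-average firing rate
#'
#' Continuous firing-rate estimate on a sliding window: windows
#' `[t, t + window)` with `t = 0, step, 2 step, ...` up to
#' `duration - window`; each value is the spike count in the window divided
#' by the window length.
#'
#' @param spike_times_s sorted spike times (seconds).
#' @param duration_s recording duration (seconds).
#' @param window_ms window size in ms (default 100).
#' @param step_ms step size in ms (default 5).
#' @return numeric vector of rates (Hz), length
#'   `floor((duration - window)/step) + 1`.
#' @export
moving_rate <- function(spike_times_s, duration_s, window_ms = 100, step_ms = 5) {
  window <- window_ms / 1000
  step <- step_ms / 1000
  stopifnot(window >= step, duration_s >= window)
  starts <- seq(0, duration_s - window + 1e-12, by = step)
  t <- sort(spike_times_s)
  # count spikes in [start, start + window) via two binary searches
  lo <- findInterval(starts, t, left.open = TRUE)
  hi <- findInterval(starts + window, t, left.open = TRUE)
  (hi - lo) / window
}

#' KL divergence between two firing-rate distributions
#'
#' Histograms the two moving-rate series on shared equal-width bins spanning
#' the pooled range, regularizes empty bins with a pseudocount of
#' `1/(n * n_bins)`, and returns `KL(P_a || P_b)` in bits (optionally the
#' symmetrized divergence).
#'
#' @param series_a,series_b numeric rate series (Hz).
#' @param n_bins number of histogram bins (default 30).
#' @param symmetric if `TRUE`, return `(KL(a||b) + KL(b||a)) / 2`.
#' @return KL divergence in bits (non-negative scalar).
#' @export
rate_distribution_kld <- function(series_a, series_b, n_bins = 30,
                                  symmetric = FALSE) {
  if (length(series_a) == 0 || length(series_b) == 0) {
    stop("cannot compare an empty rate series")
  }
  rng <- range(c(series_a, series_b))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  edges[n_bins + 1] <- edges[n_bins + 1] + 1e-9   # include the max
  histo <- function(x) {
    counts <- tabulate(findInterval(x, edges, left.open = FALSE,
                                    rightmost.closed = TRUE), n_bins)
    p <- counts + 1 / (length(x) * n_bins)        # pseudocount on empty bins
    p / sum(p)
  }
  pa <- histo(series_a)
  pb <- histo(series_b)
  if (symmetric) (kl_bits(pa, pb) + kl_bits(pb, pa)) / 2 else kl_bits(pa, pb)
}

#' Stationarity report for a set of spike trains
#'
#' Decides whether a recording's spiking statistics are stable over time.
#' Per unit: the half-split rate check and the KL divergence between the
#' moving-rate distributions of the first and second halves. At the
#' population level, the same-unit KL divergences are contrasted with KL
#' divergences between halves of random *different* unit pairs: in a
#' stationary recording the same-unit divergences are significantly smaller
#' (Welch test). The recording is flagged non-stationary when they are not.
#'
#' @param trains list of per-unit spike-time vectors (seconds), or a
#'   `unit_catalog` / `spike_trains` object.
#' @param duration_s recording duration (seconds; taken from the object when
#'   omitted).
#' @param window_ms,step_ms moving-rate parameters (defaults 100 and 5).
#' @param n_bins histogram bins for the KL divergence (default 30).
#' @param n_random_pairs number of random cross-unit pairs (default
#'   `4 * n_units`).
#' @param alpha significance level of the Welch test (default 0.05).
#' @param tol_sd half-split tolerance in Poisson SEs (default 3).
#' @param seed RNG seed for the random pairing.
#' @return object of class `stationarity_report`: per-unit data.frame
#'   (`rate_first_hz`, `rate_second_hz`, `half_split_pass`, `kld_same`),
#'   `kld_random`, `welch_p`, `stationary`, `n_units`.
#' @export
stationarity_report <- function(trains, duration_s = NULL, window_ms = 100,
                                step_ms = 5, n_bins = 30,
                                n_random_pairs = NULL, alpha = 0.05,
                                tol_sd = 3, seed = 1) {
  if (inherits(trains, "unit_catalog")) {
    duration_s <- duration_s %||% trains$duration_s
    trains <- catalog_trains(trains)
  } else if (inherits(trains, "spike_trains")) {
    duration_s <- duration_s %||% trains$duration_s
    trains <- trains$trains
  }
  stopifnot(!is.null(duration_s), length(trains) >= 2)
  n_units <- length(trains)
  half <- duration_s / 2

  rates <- lapply(trains, half_split_rates, duration_s = duration_s,
                  tol_sd = tol_sd)
  series1 <- lapply(trains, function(t) moving_rate(t[t < half], half,
                                                    window_ms, step_ms))
  series2 <- lapply(trains, function(t) moving_rate(t[t >= half] - half, half,
                                                    window_ms, step_ms))
  kld_same <- vapply(seq_len(n_units), function(i) {
    rate_distribution_kld(series1[[i]], series2[[i]], n_bins)
  }, 0)

  n_random_pairs <- n_random_pairs %||% (4L * n_units)
  kld_random <- with_seed(seed, {
    vapply(seq_len(n_random_pairs), function(k) {
      ij <- sample.int(n_units, 2)
      rate_distribution_kld(series1[[ij[1]]], series2[[ij[2]]], n_bins)
    }, 0)
  })

  degenerate <- stats::sd(kld_same) == 0 && stats::sd(kld_random) == 0
  if (degenerate) {
    warning("degenerate KL-D distributions (no variance); stationarity test uninformative")
    welch_p <- 1
  } else {
    welch_p <- stats::t.test(kld_same, kld_random,
                             alternative = "less", var.equal = FALSE)$p.value
  }
  per_unit <- data.frame(
    unit_id = seq_len(n_units),
    rate_first_hz = vapply(rates, `[[`, 0, "rate_first_hz"),
    rate_second_hz = vapply(rates, `[[`, 0, "rate_second_hz"),
    half_split_pass = vapply(rates, `[[`, TRUE, "pass"),
    kld_same = kld_same)
  # the recording passes when same-unit divergences are significantly
  # smaller AND no more than 5% of units fail the half-split gate (an
  # allowance for the 3-SE check's own false-positive rate)
  frac_fail <- mean(!per_unit$half_split_pass)
  structure(list(per_unit = per_unit, kld_random = kld_random,
                 welch_p = welch_p,
                 stationary = welch_p < alpha && frac_fail <= 0.05,
                 n_units = n_units, alpha = alpha),
            class = "stationarity_report")
}

#' @export
print.stationarity_report <- function(x, ...) {
  cat(sprintf("stationarity report: %d units, %s\n", x$n_units,
              if (x$stationary) "STATIONARY" else "NON-STATIONARY"))
  cat(sprintf("  half-split pass: %d/%d units\n",
              sum(x$per_unit$half_split_pass), x$n_units))
  cat(sprintf("  same-unit KL-D median %.4f vs random-pair %.4f bits (Welch p = %.3g)\n",
              stats::median(x$per_unit$kld_same), stats::median(x$kld_random),
              x$welch_p))
  invisible(x)
}
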