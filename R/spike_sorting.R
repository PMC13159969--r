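#' Band-pass and notch filter a voltage trace
#'
#' Isolates the spike band with a 3rd-order Butterworth band-pass
#' (500-3500 Hz) followed by a 60 Hz notch, both applied forward-backward
#' (zero phase) so waveform shape is preserved for clustering. The trace is
#' padded by reflection for `pad_s` seconds at both ends before filtering
#' and trimmed afterwards to suppress edge transients; output length equals
#' input length.
#'
#' @param trace numeric voltage series (uV).
#' @param sr_hz sampling rate in Hz.
#' @param low_hz,high_hz band edges (defaults 500 and 3500).
#' @param pad_s reflection padding in seconds (default 4).
#' @param notch_hz center of the mains notch (default 60; `NULL` disables).
#' @param order Butterworth order (default 3).
#' @return filtered trace, same length as input.
#' @export
filter_trace <- function(trace, sr_hz, low_hz = 500, high_hz = 3500,
                         pad_s = 4, notch_hz = 60, order = 3) {
  n <- length(trace)
  n_pad <- round(pad_s * sr_hz)
  if (n <= n_pad) {
    stop("trace (", n, " samples) must be longer than the padding (",
         n_pad, " samples)")
  }
  nyq <- sr_hz / 2
  stopifnot(low_hz > 0, high_hz < nyq, low_hz < high_hz)
  padded <- c(rev(trace[seq_len(n_pad)]), trace,
              rev(trace[seq.int(n - n_pad + 1L, n)]))
  bp <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  y <- signal::filtfilt(bp, padded)
  if (!is.null(notch_hz)) {
    notch <- signal::butter(2, c(notch_hz - 1, notch_hz + 1) / nyq, type = "stop")
    y <- signal::filtfilt(notch, y)
  }
  y[seq.int(n_pad + 1L, n_pad + n)]
}

#' Detect threshold-crossing spike events
#'
#' Flags samples deviating from the trace mean by more than `k_sd` standard
#' deviations and reports one event per excursion, aligned to the extremum
#' (trough for negative-going spikes). Excursions closer than `dead_time_ms`
#' are merged so a single spike cannot yield multiple events; raising `k_sd`
#' can therefore only remove events, never add them.
#'
#' @param trace filtered voltage series (uV).
#' @param sr_hz sampling rate in Hz.
#' @param k_sd detection threshold in standard deviations (default 5).
#' @param dead_time_ms minimum separation between events (default 1).
#' @param robust_sd if `TRUE`, estimate the SD as 1.4826 x MAD instead of
#'   the literal standard deviation about the mean (default `FALSE`).
#' @return numeric vector of event times in seconds (extremum-aligned).
#' @export
detect_events <- function(trace, sr_hz, k_sd = 5, dead_time_ms = 1,
                          robust_sd = FALSE) {
  mu <- mean(trace)
  s <- if (robust_sd) stats::mad(trace) else stats::sd(trace)
  if (s == 0) {
    warning("zero-variance trace: no events")
    return(numeric(0))
  }
  dev <- abs(trace - mu)
  above <- dev > k_sd * s
  if (!any(above)) return(numeric(0))
  # group contiguous supra-threshold samples into excursions
  d <- diff(c(FALSE, above))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  if (length(ends) < length(starts)) ends <- c(ends, length(trace))
  peaks <- vapply(seq_along(starts), function(k) {
    seg <- starts[k]:ends[k]
    seg[which.max(dev[seg])]
  }, 0L)
  # enforce dead time, keeping the larger excursion of any close pair
  dead <- round(dead_time_ms / 1000 * sr_hz)
  keep <- integer(0)
  last <- -Inf
  for (p in peaks) {
    if (p - last >= dead) {
      keep <- c(keep, p)
      last <- p
    } else if (dev[p] > dev[keep[length(keep)]]) {
      keep[length(keep)] <- p
      last <- p
    }
  }
  (keep - 1L) / sr_hz
}

#' Extract per-event waveform snippets
#'
#' Cuts a fixed window around each event time from one or more channels.
#' Multi-channel snippets are concatenated channel-by-channel, which is the
#' representation fed to PCA. Events whose window would run off either end
#' of the recording are dropped.
#'
#' @param samples a channels x samples matrix (or a single trace vector).
#' @param event_times_s event times in seconds (extremum-aligned).
#' @param sr_hz sampling rate.
#' @param n_pre,n_post samples before / after the alignment point
#'   (defaults 13, 24: 1 ms + ~2 ms at 12.5 kHz).
#' @param source_channel channel the events were detected on (metadata).
#' @return object of class `waveform_set`: `waveforms` (events x
#'   (window x channels) matrix), `event_times_s`, `n_pre`, `n_post`,
#'   `n_channels`, `source_channel`, `sr_hz`.
#' @export
extract_waveforms <- function(samples, event_times_s, sr_hz,
                              n_pre = 13, n_post = 24, source_channel = 1L) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  idx <- round(event_times_s * sr_hz) + 1L
  win <- n_pre + n_post + 1L
  ok <- idx - n_pre >= 1L & idx + n_post <= ncol(samples)
  idx <- idx[ok]
  W <- matrix(0, length(idx), win * nrow(samples))
  for (e in seq_along(idx)) {
    snip <- samples[, (idx[e] - n_pre):(idx[e] + n_post), drop = FALSE]
    W[e, ] <- as.vector(t(snip))
  }
  structure(list(waveforms = W, event_times_s = event_times_s[ok],
                 n_pre = n_pre, n_post = n_post,
                 n_channels = nrow(samples), source_channel = source_channel,
                 sr_hz = sr_hz),
            class = "waveform_set")
}

#' Reject symmetric high-frequency noise events
#'
#' Periodic noise caught by the amplitude threshold looks time-symmetric
#' and has nearly equal positive and negative excursions, unlike an action
#' potential's sharp trough and slow recovery. An event is rejected when
#' both hold on its source-channel snippet: the Pearson correlation between
#' the waveform and its time reverse (reflected about the alignment
#' extremum) exceeds `symmetry_corr_threshold`, and the absolute difference
#' between `|peak|` and `|trough|` is below `peak_trough_diff` (uV).
#'
#' @param wset a `waveform_set`.
#' @param symmetry_corr_threshold correlation threshold (default 0.9).
#' @param peak_trough_diff peak/trough amplitude-difference threshold in uV
#'   (default 8).
#' @return the filtered `waveform_set`, with attribute `n_rejected`.
#' @export
reject_symmetric_noise <- function(wset, symmetry_corr_threshold = 0.9,
                                   peak_trough_diff = 8) {
  W <- wset$waveforms
  if (nrow(W) == 0) return(wset)
  win <- wset$n_pre + wset$n_post + 1L
  src <- wset$source_channel
  cols <- ((src - 1L) * win + 1L):(src * win)
  keep <- vapply(seq_len(nrow(W)), function(e) {
    w <- W[e, cols]
    # reflect about the extremum so symmetry is phase-independent
    m <- which.max(abs(w - mean(w)))
    k <- min(m - 1L, length(w) - m)
    sym <- if (k >= 2) {
      seg <- w[(m - k):(m + k)]
      suppressWarnings(stats::cor(seg, rev(seg)))
    } else {
      1
    }
    if (is.na(sym)) sym <- 1            # flat snippet: treat as noise
    amp_diff <- abs(max(w) - abs(min(w)))
    !(sym > symmetry_corr_threshold && amp_diff < peak_trough_diff)
  }, TRUE)
  out <- wset
  out$waveforms <- W[keep, , drop = FALSE]
  out$event_times_s <- wset$event_times_s[keep]
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Project waveforms to PCA space and cluster by Gaussian mixture
#'
#' Projects the (concatenated multi-channel) waveforms onto their leading
#' principal components and clusters the scores with an EM-fitted Gaussian
#' mixture model, choosing the number of components by BIC over
#' `1..max_clusters`.
#'
#' @param wset a `waveform_set` with at least 2 events.
#' @param n_components number of principal components (default 2).
#' @param max_clusters largest mixture size considered (default 8).
#' @param seed RNG seed (clustering is deterministic given the seed).
#' @return integer vector of cluster labels, one per event, with attribute
#'   `scores` (the PCA projection) and `n_clusters`.
#' @export
project_and_cluster <- function(wset, n_components = 2, max_clusters = 8,
                                seed = 1) {
  W <- wset$waveforms
  n <- nrow(W)
  if (n < 2) stop("need at least 2 events to cluster")
  if (n <= max_clusters) {
    labels <- rep(1L, n)
    attr(labels, "n_clusters") <- 1L
    return(labels)
  }
  sds <- apply(W, 2, stats::sd)
  if (all(sds == 0)) {                       # all events identical
    labels <- rep(1L, n)
    attr(labels, "scores") <- matrix(0, n, n_components)
    attr(labels, "n_clusters") <- 1L
    return(labels)
  }
  pc <- stats::prcomp(W, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  mclustBIC <- mclust::mclustBIC      # Mclust resolves this in the caller
  fit <- with_seed(seed,
    mclust::Mclust(scores, G = seq_len(max_clusters), verbose = FALSE))
  labels <- as.integer(fit$classification)
  attr(labels, "scores") <- scores
  attr(labels, "n_clusters") <- fit$G
  labels
}

#' Merge clusters with similar mean waveforms
#'
#' Groups clusters whose mean-waveform Pearson correlation exceeds
#' `corr_threshold` to prevent overclustering. Merging takes the transitive
#' closure of the above-threshold pairs (connected components), so the
#' result does not depend on the order in which pairs are examined, and
#' re-merging a merged catalog changes nothing.
#'
#' @param mean_waveforms matrix, one row per cluster (concatenated-channel
#'   mean waveform).
#' @param corr_threshold merge threshold on Pearson correlation
#'   (default 0.8).
#' @return integer vector mapping each input cluster to its merged unit id
#'   (1-based, consecutive).
#' @export
merge_similar_clusters <- function(mean_waveforms, corr_threshold = 0.8) {
  n <- nrow(mean_waveforms)
  if (n == 0) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    cm <- suppressWarnings(stats::cor(t(mean_waveforms)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (!is.na(cm[i, j]) && cm[i, j] > corr_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, sort(unique(roots)))
}

#' Interspike-interval validation of a unit
#'
#' A well-isolated unit respects the absolute refractory period: at most a
#' small fraction of its interspike intervals may fall below `refractory_ms`.
#'
#' @param spike_times_s sorted spike times in seconds.
#' @param max_violation_fraction failure threshold on the violation fraction
#'   (default 0.05).
#' @param refractory_ms refractory period in milliseconds (default 2.5).
#' @return list `pass` (logical) and `violation_fraction`.
#' @export
validate_isi <- function(spike_times_s, max_violation_fraction = 0.05,
                         refractory_ms = 2.5) {
  if (length(spike_times_s) < 2) {
    warning("fewer than 2 spikes: ISI check passes vacuously")
    return(list(pass = TRUE, violation_fraction = 0))
  }
  isi <- diff(spike_times_s)
  frac <- mean(isi < refractory_ms / 1000)
  list(pass = frac < max_violation_fraction, violation_fraction = frac)
}

# A unit whose mean waveform has multiple large local extrema is a compound
# spike (overlapping cells); flag for exclusion.
is_compound_waveform <- function(w, frac = 0.5) {
  dev <- abs(w - stats::median(w))
  big <- dev > frac * max(dev)
  # count local maxima of |deviation| that are individually > frac of global
  n_ext <- 0L
  for (i in 2:(length(w) - 1)) {
    if (big[i] && dev[i] >= dev[i - 1] && dev[i] >= dev[i + 1]) {
      n_ext <- n_ext + 1L
      # skip plateau
    }
  }
  n_ext > 1L
}

#' Sort spikes from a multichannel voltage recording
#'
#' Runs the full per-channel sorting chain and cross-channel cleanup:
#' filter ([filter_trace()]), detect ([detect_events()]), extract
#' multi-channel snippets, reject symmetric noise, PCA + Gaussian-mixture
#' clustering ([project_and_cluster()]), within-channel merging of
#' correlated clusters ([merge_similar_clusters()]), cross-channel
#' deduplication of units seen on neighboring channels (coincident spikes
#' and correlated waveforms), compound-spike exclusion, and ISI validation.
#'
#' @param recording a `voltage_recording`.
#' @param config a [pipeline_config()]; individual fields can be overridden
#'   by the remaining arguments.
#' @param verbose print per-stage counts (default `FALSE`).
#' @return object of class `unit_catalog`: list `units`, each with
#'   `spike_times_s`, `mean_waveforms` (channels x window), `home_channel`,
#'   `qc` (`isi_pass`, `isi_violation_fraction`, `compound_pass`), plus the
#'   `config` used and the channel coordinates.
#' @export
sort_spikes <- function(recording, config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(recording, "voltage_recording"))
  sr <- recording$sampling_rate_hz
  cfg <- config
  n_ch <- nrow(recording$samples)
  say <- function(...) if (verbose) message(sprintf(...))

  filtered <- t(apply(recording$samples, 1, filter_trace, sr_hz = sr,
                      low_hz = cfg$filter_low_hz, high_hz = cfg$filter_high_hz,
                      pad_s = cfg$filter_pad_s, notch_hz = cfg$notch_hz))

  units <- list()
  win <- cfg$waveform_pre + cfg$waveform_post + 1L
  for (ch in seq_len(n_ch)) {
    ev <- detect_events(filtered[ch, ], sr, k_sd = cfg$k_sd,
                        dead_time_ms = cfg$dead_time_ms,
                        robust_sd = cfg$robust_sd)
    if (length(ev) < 2) next
    wset <- extract_waveforms(filtered, ev, sr, n_pre = cfg$waveform_pre,
                              n_post = cfg$waveform_post, source_channel = ch)
    wset <- reject_symmetric_noise(wset, cfg$symmetry_corr_threshold,
                                   cfg$peak_trough_diff)
    if (nrow(wset$waveforms) < 2) next
    say("channel %d: %d events after noise rejection", ch, nrow(wset$waveforms))
    labels <- project_and_cluster(wset, cfg$pca_components, cfg$max_clusters,
                                  seed = cfg$seed + ch)
    means <- t(vapply(sort(unique(labels)), function(l) {
      colMeans(wset$waveforms[labels == l, , drop = FALSE])
    }, numeric(ncol(wset$waveforms))))
    merged <- merge_similar_clusters(means, cfg$merge_corr_threshold)
    for (m in sort(unique(merged))) {
      sel <- labels %in% which(merged == m)
      units[[length(units) + 1]] <- list(
        spike_times_s = sort(wset$event_times_s[sel]),
        mean_waveforms = matrix(colMeans(wset$waveforms[sel, , drop = FALSE]),
                                nrow = n_ch, byrow = TRUE),
        home_channel = ch)
    }
  }

  # cross-channel deduplication: same neuron picked up on neighboring
  # channels shows coincident spikes and correlated waveforms
  if (length(units) > 1) {
    n_u <- length(units)
    mw <- t(vapply(units, function(u) as.vector(t(u$mean_waveforms)),
                   numeric(n_ch * win)))
    keep <- rep(TRUE, n_u)
    coincident <- function(a, b, tol = 5e-4) {
      if (length(a) == 0 || length(b) == 0) return(0)
      hits <- vapply(a, function(t) any(abs(b - t) <= tol), TRUE)
      mean(hits)
    }
    ord <- order(vapply(units, function(u) -length(u$spike_times_s), 0))
    for (ii in seq_along(ord)) {
      i <- ord[ii]
      if (!keep[i]) next
      for (jj in seq_along(ord)) {
        j <- ord[jj]
        if (jj <= ii || !keep[j]) next
        wc <- suppressWarnings(stats::cor(mw[i, ], mw[j, ]))
        if (!is.na(wc) && wc > cfg$merge_corr_threshold &&
            coincident(units[[j]]$spike_times_s,
                       units[[i]]$spike_times_s) > 0.5) {
          keep[j] <- FALSE           # absorb duplicate into the larger unit
        }
      }
    }
    units <- units[keep]
  }

  # quality control: minimum yield, compound-spike exclusion, ISI validation
  for (k in seq_along(units)) {
    u <- units[[k]]
    home_w <- u$mean_waveforms[u$home_channel, ]
    compound_pass <- !is_compound_waveform(home_w)
    isi <- suppressWarnings(
      validate_isi(u$spike_times_s, cfg$isi_max_violation, cfg$isi_refractory_ms))
    units[[k]]$qc <- list(isi_pass = isi$pass,
                          isi_violation_fraction = isi$violation_fraction,
                          compound_pass = compound_pass,
                          yield_pass = length(u$spike_times_s) >= cfg$min_spikes)
  }
  valid <- vapply(units, function(u) {
    u$qc$isi_pass && u$qc$compound_pass && u$qc$yield_pass
  }, TRUE)
  say("%d units sorted, %d pass QC", length(units), sum(valid))
  structure(list(units = units[valid],
                 rejected_units = units[!valid],
                 channel_coords = recording$channel_coords,
                 duration_s = recording$duration_s,
                 config = cfg),
            class = "unit_catalog")
}

#' @export
print.unit_catalog <- function(x, ...) {
  cat(sprintf("unit catalog: %d valid units (%d rejected by QC) over %.1f s\n",
              length(x$units), length(x$rejected_units), x$duration_s))
  for (i in seq_along(x$units)) {
    u <- x$units[[i]]
    cat(sprintf("  unit %d: %d spikes (%.2f Hz), home channel %d\n",
                i, length(u$spike_times_s),
                length(u$spike_times_s) / x$duration_s, u$home_channel))
  }
  invisible(x)
}

#' Spike trains of a sorted catalog
#'
#' @param catalog a `unit_catalog`.
#' @return named list of spike-time vectors (seconds).
#' @export
catalog_trains <- function(catalog) {
  tr <- lapply(catalog$units, `[[`, "spike_times_s")
  names(tr) <- paste0("unit", seq_along(tr))
  tr
}
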