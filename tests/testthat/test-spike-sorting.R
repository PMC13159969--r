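sr <- 12500

test_that("band-pass filter preserves passband tones and kills DC and mains", {
  t <- seq(0, 8, by = 1 / sr)
  # 1,500 Hz tone inside the passband: amplitude preserved within 5%
  tone <- sin(2 * pi * 1500 * t)
  out <- filter_trace(tone, sr, pad_s = 2)
  mid <- seq(round(length(out) * 0.25), round(length(out) * 0.75))
  expect_lt(abs(max(abs(out[mid])) - 1), 0.05)

  # DC is outside the passband
  dc <- filter_trace(rep(3, length(t)), sr, pad_s = 2)
  expect_lt(max(abs(dc)), 1e-6)

  # 60 Hz mains: attenuated below 5%
  mains <- sin(2 * pi * 60 * t)
  out60 <- filter_trace(mains, sr, pad_s = 2)
  expect_lt(max(abs(out60[mid])), 0.05)
})

test_that("filtering preserves length and is near-idempotent in the passband", {
  set.seed(2)
  x <- stats::rnorm(sr * 6)
  y1 <- filter_trace(x, sr, pad_s = 2)
  expect_length(y1, length(x))
  # applying the filter twice ~ once for an in-band tone (gain^2 within 10%)
  t <- seq(0, 6, by = 1 / sr)[-1]
  tone <- sin(2 * pi * 2000 * t)
  g1 <- max(abs(filter_trace(tone, sr, pad_s = 2)))
  g2 <- max(abs(filter_trace(filter_trace(tone, sr, pad_s = 2), sr, pad_s = 2)))
  expect_lt(abs(g2 - g1^2), 0.1)
  expect_error(filter_trace(stats::rnorm(100), sr, pad_s = 2), "longer than the padding")
})

test_that("event detection matches the Gaussian tail rate and finds planted spikes", {
  set.seed(7)
  n <- 15 * 60 * sr                     # 15 minutes
  noise <- stats::rnorm(n)
  ev <- detect_events(noise, sr, k_sd = 5)
  lambda <- n * 2 * stats::pnorm(-5)    # expected false positives (~6.4)
  expect_gte(length(ev), stats::qpois(0.001, lambda))
  expect_lte(length(ev), stats::qpois(0.999, lambda))

  # one injected 8-SD spike is recovered at its time within 1 sample
  x <- stats::rnorm(sr)                  # 1 s of unit-SD noise
  x[6250] <- -8
  ev2 <- detect_events(x, sr, k_sd = 5)
  expect_true(any(abs(ev2 - 6249 / sr) <= 1 / sr))

  # degenerate traces
  expect_warning(ev0 <- detect_events(rep(0, 1000), sr), "zero-variance")
  expect_length(ev0, 0)
})

test_that("detection count is monotone nonincreasing in the threshold", {
  set.seed(8)
  x <- stats::rnorm(sr * 120)
  spikes <- sort(sample(seq(100, length(x) - 100), 200))
  x[spikes] <- x[spikes] - 7
  counts <- vapply(seq(4.5, 5.5, by = 0.25), function(k) {
    length(detect_events(x, sr, k_sd = k))
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("symmetric-noise rejection keeps spikes and drops oscillations", {
  w_spike <- spike_template(40)
  win <- length(w_spike)
  t <- seq_len(win)
  w_sine <- 40 * sin(2 * pi * t / 12)   # symmetric, equal peak and trough
  set.seed(3)
  n_each <- 50
  W <- rbind(t(replicate(n_each, w_sine + stats::rnorm(win, sd = 0.5))),
             t(replicate(n_each, w_spike + stats::rnorm(win, sd = 0.5))))
  wset <- structure(list(waveforms = W, event_times_s = seq_len(2 * n_each) / 100,
                         n_pre = 13, n_post = 24, n_channels = 1,
                         source_channel = 1, sr_hz = sr),
                    class = "waveform_set")
  out <- reject_symmetric_noise(wset, symmetry_corr_threshold = 0.9,
                                peak_trough_diff = 8)
  expect_equal(nrow(out$waveforms), n_each)              # exactly the spikes
  expect_true(all(out$event_times_s > n_each / 100))     # the second block
})

test_that("PCA + Gaussian mixture separates well-separated waveform clouds", {
  set.seed(4)
  wa <- spike_template(60)
  wb <- -rev(spike_template(60))        # very different shape
  n <- 150
  W <- rbind(t(replicate(n, wa + stats::rnorm(length(wa), sd = 1))),
             t(replicate(n, wb + stats::rnorm(length(wb), sd = 1))))
  wset <- structure(list(waveforms = W, event_times_s = seq_len(2 * n) / 100,
                         n_pre = 13, n_post = 24, n_channels = 1,
                         source_channel = 1, sr_hz = sr),
                    class = "waveform_set")
  labels <- project_and_cluster(wset, n_components = 2, seed = 1)
  expect_equal(attr(labels, "n_clusters"), 2)
  truth <- rep(1:2, each = n)
  agreement <- max(mean(labels == truth), mean(labels == 3 - truth))
  expect_gte(agreement, 0.99)

  # all-identical events collapse to one cluster
  W1 <- matrix(rep(wa, each = 20), nrow = 20)
  wset1 <- structure(list(waveforms = W1, event_times_s = seq_len(20) / 100,
                          n_pre = 13, n_post = 24, n_channels = 1,
                          source_channel = 1, sr_hz = sr),
                     class = "waveform_set")
  labels1 <- project_and_cluster(wset1, seed = 1)
  expect_equal(attr(labels1, "n_clusters"), 1)
})

test_that("cluster merging takes the transitive closure and is idempotent", {
  w <- spike_template(50)
  # identical waveforms merge; orthogonal ones do not
  expect_equal(merge_similar_clusters(rbind(w, w)), c(1L, 1L))
  t <- seq_along(w)
  expect_equal(merge_similar_clusters(rbind(sin(2 * pi * t / 19),
                                            cos(2 * pi * t / 19))), c(1L, 2L))

  # chain A~B, B~C with A!~C merges all three through the closure;
  # engineer exact pairwise correlations from a zero-mean orthonormal pair
  n <- 40
  u <- sin(2 * pi * seq_len(n) / n); u <- u / sqrt(sum(u^2))
  v <- cos(2 * pi * seq_len(n) / n); v <- v - mean(v); v <- v / sqrt(sum(v^2))
  A <- u
  B <- cos(pi / 6) * u + sin(pi / 6) * v    # cor(A,B) = cos 30 deg = 0.866
  C <- cos(pi / 3) * u + sin(pi / 3) * v    # cor(A,C) = cos 60 deg = 0.5
  cors <- stats::cor(t(rbind(A, B, C)))
  expect_gt(cors[1, 2], 0.8); expect_gt(cors[2, 3], 0.8)
  expect_lt(cors[1, 3], 0.8)
  merged <- merge_similar_clusters(rbind(A, B, C), 0.8)
  expect_equal(merged, c(1L, 1L, 1L))

  # idempotence: merging the merged means changes nothing
  groups <- merge_similar_clusters(rbind(A, B, C), 0.8)
  mean_merged <- colMeans(rbind(A, B, C)[groups == 1, , drop = FALSE])
  expect_equal(merge_similar_clusters(matrix(mean_merged, 1), 0.8), 1L)
})

test_that("ISI validation counts refractory violations correctly", {
  # regular 10 Hz train: no violations
  r <- validate_isi(seq(0, 10, by = 0.1))
  expect_true(r$pass); expect_equal(r$violation_fraction, 0)

  # all ISIs at 1 ms: total violation
  r2 <- validate_isi(seq(0, 0.099, by = 0.001))
  expect_false(r2$pass); expect_equal(r2$violation_fraction, 1)

  # 100 spikes, exactly 4 ISIs at 2 ms: fraction 4/99, passes
  t <- cumsum(c(0, rep(0.05, 95), rep(0.002, 4)))
  r3 <- validate_isi(sort(t))
  expect_equal(r3$violation_fraction, 4 / 99)
  expect_true(r3$pass)

  expect_warning(validate_isi(0.5), "fewer than 2")
})

test_that("end-to-end sorting recovers planted units with high fidelity", {
  fx <- planted_recording(duration_s = 40, noise_sd_uV = 8, seed = 15)
  catalog <- sort_spikes(fx$recording, pipeline_config())
  expect_equal(length(catalog$units), 3)
  sc <- score_sorting(catalog, fx$truth, tol_ms = 1)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.95)
})
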