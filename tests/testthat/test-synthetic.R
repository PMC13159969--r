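test_that("exact Ising sampler reproduces symmetry and independence limits", {
  # K = 1, h = 0: spike probability 1/2
  r1 <- sample_ising(ising_params(0), 1e6, seed = 11)
  expect_lt(abs(mean(r1) - 0.5), 0.002)

  # K = 2, J = 0: marginals follow logit(h), covariance vanishes
  p2 <- ising_params(h = stats::qlogis(c(0.2, 0.7)))
  r2 <- sample_ising(p2, 2e5, seed = 12)
  expect_lt(abs(mean(r2[1, ]) - 0.2), 0.005)
  expect_lt(abs(mean(r2[2, ]) - 0.7), 0.005)
  expect_lt(abs(stats::cov(r2[1, ], r2[2, ])), 0.004)
})

test_that("sampled word frequencies match the enumerated Boltzmann oracle", {
  set.seed(42)
  K <- 3
  h <- stats::rnorm(K)
  J <- matrix(0, K, K)
  J[upper.tri(J)] <- stats::rnorm(3, sd = 0.6)
  J <- J + t(J)
  n <- 1e6
  raster <- sample_ising(ising_params(h, J), n, seed = 13)
  words <- colSums(raster * 2^(0:(K - 1)))
  emp <- tabulate(words + 1, 2^K) / n

  orac <- oracle_ising_probs(h, J)
  # every word frequency within 3 Monte Carlo standard errors
  se <- sqrt(orac$probs * (1 - orac$probs) / n)
  expect_true(all(abs(emp - orac$probs) <= 3 * se))
  # and a chi-square goodness of fit does not reject
  chi <- sum((n * emp - n * orac$probs)^2 / (n * orac$probs))
  expect_gt(stats::pchisq(chi, df = 2^K - 1, lower.tail = FALSE), 0.001)
})

test_that("sampler refuses oversized or malformed inputs", {
  expect_error(sample_ising(ising_params(rep(0, 17)), 10, seed = 1), "K <= 16")
  expect_error(ising_params(c(0, 0), matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(ising_params(c(0, 0), matrix(c(1, 0, 0, 1), 2)), "diagonal")
})

test_that("dichotomized Gaussian trains hit target rates and correlations", {
  # independence: negligible measured correlation
  ind <- generate_correlated_trains(c(1, 1), diag(2), 1000, seed = 21)
  r_ind <- stats::cor(ind$raster[1, ], ind$raster[2, ])
  expect_lt(abs(r_ind), 0.05)

  # perfect latent coupling at equal rates: identical trains
  dup <- generate_correlated_trains(c(2, 2), matrix(1, 2, 2), 200, seed = 22)
  expect_identical(dup$raster[1, ], dup$raster[2, ])
  expect_equal(stats::cor(dup$raster[1, ], dup$raster[2, ]), 1)

  # latent 0.5 at 2 Hz: measured binary correlation matches the
  # bivariate-normal orthant-probability closed form
  C <- matrix(0.5, 3, 3); diag(C) <- 1
  g <- generate_correlated_trains(rep(2, 3), C, 2000, bin_s = 0.01, seed = 23)
  expected <- oracle_dg_correlation(0.02, 0.02, 0.5)
  cm <- stats::cor(t(g$raster))
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_lt(abs(cm[pair[1], pair[2]] - expected), 0.02)
  }
  # rates within sampling error of 2 Hz
  expect_true(all(abs(lengths(g$trains) / g$duration_s - 2) < 0.2))
})

test_that("dichotomized Gaussian correlation is monotone in the latent one", {
  measured <- vapply(c(0, 0.3, 0.6, 0.9), function(rho) {
    C <- matrix(rho, 2, 2); diag(C) <- 1
    g <- generate_correlated_trains(c(3, 3), C, 1500, seed = 24)
    stats::cor(g$raster[1, ], g$raster[2, ])
  }, 0)
  expect_true(all(diff(measured) > 0))
})

test_that("generator rejects infeasible rates and bad correlation matrices", {
  expect_error(generate_correlated_trains(150, diag(1), 10), "infeasible")
  bad <- matrix(c(1, 2, 2, 1), 2)   # |rho| > 1: not PSD
  expect_error(generate_correlated_trains(c(1, 1), bad, 10), "semidefinite")
})

test_that("generators are bit-reproducible given the seed", {
  a <- generate_correlated_trains(c(2, 1), diag(2), 100, seed = 9)
  b <- generate_correlated_trains(c(2, 1), diag(2), 100, seed = 9)
  expect_identical(a$trains, b$trains)
  ra <- sample_ising(ising_params(c(-1, 0)), 1000, seed = 4)
  rb <- sample_ising(ising_params(c(-1, 0)), 1000, seed = 4)
  expect_identical(unclass(ra), unclass(rb))
})

test_that("binarizing jittered spike times recovers the generated raster", {
  g <- generate_correlated_trains(c(4, 3), diag(2), 300, seed = 31)
  r <- binarize(g$trains, g$duration_s, bin_ms = 10)
  expect_equal(unname(unclass(r)[, ]), unname(unclass(g$raster)[, ]))
})

test_that("synthesized voltage is noise-only without units and exact without noise", {
  grid <- mea_grid(2, 300)
  # zero units: pure Gaussian noise at the stated SD
  gt0 <- ground_truth(list(), data.frame(x_um = numeric(), y_um = numeric()), 2)
  rec0 <- synthesize_voltage(gt0, list(), grid, noise_sd_uV = 5, seed = 3)
  sds <- apply(rec0$samples, 1, stats::sd)
  expect_true(all(abs(sds - 5) < 0.1))

  # one unit at a channel location, zero noise: that channel's trace equals
  # the template at the spike time, decayed copies elsewhere
  w <- spike_template(80)
  gt1 <- ground_truth(list(u1 = 1.0), data.frame(x_um = 0, y_um = 0), 2)
  rec1 <- synthesize_voltage(gt1, list(w), grid, noise_sd_uV = 0, seed = 3)
  n_pre <- which.min(w) - 1
  i0 <- round(1.0 * 12500) + 1 - n_pre
  seg <- rec1$samples[1, i0:(i0 + length(w) - 1)]
  expect_equal(seg, w)
  d <- 300
  expect_equal(rec1$samples[2, i0:(i0 + length(w) - 1)], w / (1 + d / 150))
  expect_true(all(rec1$samples[1, -(i0:(i0 + length(w) - 1))] == 0))

  # duplicated spike times are rejected
  gt_bad <- ground_truth(list(u1 = c(0.5, 0.8)), data.frame(x_um = 0, y_um = 0), 2)
  gt_bad$trains[[1]] <- c(0.5, 0.5)
  expect_error(synthesize_voltage(gt_bad, list(w), grid, 0), "identical spike times")
})

test_that("spike template has a single dominant trough and is asymmetric", {
  w <- spike_template(80)
  expect_equal(min(w), -80)
  # single dominant negative peak
  dev <- abs(w - stats::median(w))
  big_minima <- sum(diff(sign(diff(w))) > 0 & dev[-c(1, length(w))] > 0.5 * max(dev))
  expect_equal(big_minima, 1)
  # asymmetric: far from its time reverse
  expect_lt(stats::cor(w, rev(w)), 0.9)
})
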