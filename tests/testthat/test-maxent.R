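test_that("train/test split is disjoint, exhaustive and marginal-preserving", {
  r <- random_raster(3, 1000)
  halves <- split_train_test(r)
  expect_equal(ncol(halves$train), 500)
  expect_equal(ncol(halves$test), 500)

  r_odd <- random_raster(3, 999)
  h2 <- split_train_test(r_odd)
  expect_equal(abs(ncol(h2$train) - ncol(h2$test)), 1)
  expect_equal(ncol(h2$train) + ncol(h2$test), 999)

  # stationary generator: train and test marginals agree within sampling error
  set.seed(61)
  big <- random_raster(4, 20000, p = c(0.1, 0.2, 0.3, 0.4))
  h3 <- split_train_test(big)
  se <- sqrt(0.4 * 0.6 / 10000)
  expect_true(all(abs(rowMeans(h3$train) - rowMeans(h3$test)) < 4 * se))
})

test_that("the model distribution hits its closed forms", {
  # h = 0, J = 0: uniform over all words
  expect_equal(model_word_distribution(ising_params(c(0, 0, 0))),
               rep(1 / 8, 8))
  # K = 1, h = log 3: P(1) = 3/4
  p <- model_word_distribution(ising_params(log(3)))
  expect_equal(p[2], 0.75)
  # matches the independent enumeration oracle on a random model
  set.seed(62)
  h <- stats::rnorm(4); J <- matrix(0, 4, 4)
  J[upper.tri(J)] <- stats::rnorm(6, sd = 0.5); J <- J + t(J)
  expect_equal(model_word_distribution(ising_params(h, J)),
               oracle_ising_probs(h, J)$probs, tolerance = 1e-12)
})

test_that("fitting independent data drives J to zero and h to the logit rate", {
  set.seed(63)
  p_true <- c(0.25, 0.35, 0.45)
  r <- random_raster(3, 1e5, p = p_true)
  fit <- fit_pairwise_ising(r)
  expect_true(fit$converged)
  expect_true(all(abs(fit$params$J[upper.tri(fit$params$J)]) < 0.05))
  # h matches the logit of the *empirical* rate exactly at J ~ 0, and the
  # logit of the generating rate within sampling error
  expect_true(all(abs(fit$params$h - stats::qlogis(p_true)) < 0.05))
})

test_that("the saturated K = 2 fit matches the log-odds closed form", {
  # construct a raster with prescribed joint counts (all positive)
  n <- c(n00 = 400, n01 = 150, n10 = 250, n11 = 200)
  cols <- cbind(matrix(0, 2, n["n00"]),
                rbind(rep(0, n["n01"]), rep(1, n["n01"])),
                rbind(rep(1, n["n10"]), rep(0, n["n10"])),
                matrix(1, 2, n["n11"]))
  r <- meapop:::new_raster(cols, 0.01)
  fit <- fit_pairwise_ising(r, tol = 1e-9)
  h1 <- log(n[["n10"]] / n[["n00"]])
  h2 <- log(n[["n01"]] / n[["n00"]])
  J12 <- log(n[["n11"]] * n[["n00"]] / (n[["n10"]] * n[["n01"]]))
  expect_equal(fit$params$h[1], h1, tolerance = 1e-6)
  expect_equal(fit$params$h[2], h2, tolerance = 1e-6)
  expect_equal(fit$params$J[1, 2], J12, tolerance = 1e-6)
  # saturated model reproduces its own training distribution: KL = 0
  expect_lt(evaluate_fit(fit, r), 1e-10)
})

test_that("parameters are recovered within 3 SE from exact-sampler data", {
  set.seed(64)
  K <- 5
  h <- stats::runif(K, -2.5, -0.5)
  J <- matrix(0, K, K)
  J[upper.tri(J)] <- stats::runif(K * (K - 1) / 2, -0.6, 0.9)
  J <- J + t(J)
  params <- ising_params(h, J)
  n <- 1e5
  r <- sample_ising(params, n, seed = 65)
  fit <- fit_pairwise_ising(r)
  expect_true(fit$converged)

  # oracle SEs from the inverse Fisher information at the true parameters,
  # assembled by direct enumeration independent of the package internals
  orac <- oracle_ising_probs(h, J)
  feats <- cbind(orac$words,
                 do.call(cbind, lapply(seq_len(K - 1), function(i) {
                   sapply((i + 1):K, function(j) orac$words[, i] * orac$words[, j])
                 })))
  # reorder pair columns to (1,2),(1,3),(2,3),... upper-tri column order
  pair_order <- do.call(rbind, lapply(seq_len(K - 1), function(i) {
    cbind(i, (i + 1):K)
  }))
  ut <- which(upper.tri(J), arr.ind = TRUE)
  ut <- ut[order(ut[, 2], ut[, 1]), ]
  perm <- match(paste(ut[, 1], ut[, 2]), paste(pair_order[, 1], pair_order[, 2]))
  feats <- cbind(feats[, seq_len(K)], feats[, K + perm, drop = FALSE])
  mu <- colSums(feats * orac$probs)
  I_fisher <- t(feats) %*% (feats * orac$probs) - tcrossprod(mu)
  se <- sqrt(diag(solve(I_fisher)) / n)

  theta_true <- c(h, J[upper.tri(J)])
  theta_fit <- c(fit$params$h, fit$params$J[upper.tri(fit$params$J)])
  expect_true(all(abs(theta_fit - theta_true) <= 3 * se))
})

test_that("every converged fit matches its training moments to tolerance", {
  set.seed(66)
  for (i in 1:5) {
    K <- sample(2:6, 1)
    r <- random_raster(K, 2000)
    fit <- fit_pairwise_ising(r, tol = 1e-6)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$train_moments - fit$model_moments)), 1e-6)
    # maximum-entropy property: model entropy >= empirical train entropy
    H_model <- -sum(fit$model_probs * log2(fit$model_probs))
    expect_gte(H_model + 1e-9, word_entropy(r))
  }
})

test_that("degenerate units are clipped with a warning instead of diverging", {
  cols <- rbind(rep(0, 100), stats::rbinom(100, 1, 0.3))
  r <- meapop:::new_raster(cols, 0.01)
  expect_warning(fit <- fit_pairwise_ising(r), "clipped")
  expect_true(all(is.finite(fit$params$h)))
})

test_that("held-out KL divergence identifies model mismatch", {
  # model equal to the empirical distribution: KL = 0
  r <- random_raster(2, 256)
  emp <- empirical_word_distribution(r)
  expect_equal(evaluate_fit(pmax(emp, 1e-12) / sum(pmax(emp, 1e-12)), r), 0,
               tolerance = 1e-6)

  # empirical {00: .5, 11: .5} against a uniform K = 2 model: 1 bit
  cols <- cbind(matrix(0, 2, 50), matrix(1, 2, 50))
  r2 <- meapop:::new_raster(cols, 0.01)
  expect_equal(evaluate_fit(rep(0.25, 4), r2), 1)

  # pairwise-generated data: KL -> 0 with n; planted third-order synchrony
  # stays bounded away from zero at matched n
  set.seed(67)
  params <- ising_params(c(-2, -1.5, -2, -2, -1.8), matrix(0, 5, 5))
  klds_pw <- vapply(c(2000, 20000), function(n) {
    r <- sample_ising(params, n, seed = n)
    halves <- split_train_test(r)
    evaluate_fit(fit_pairwise_ising(halves$train), halves$test)
  }, 0)
  expect_lt(klds_pw[2], klds_pw[1])

  # strict triplet synchrony among units 1-3 over sparse independent
  # background: not expressible by any pairwise model
  n <- 20000
  sync <- stats::rbinom(n, 1, 0.12)
  m <- matrix(stats::rbinom(5 * n, 1, 0.05), 5, n)
  m[1:3, sync == 1] <- 1L
  halves3 <- split_train_test(meapop:::new_raster(m, 0.01))
  kld_triplet <- evaluate_fit(suppressWarnings(fit_pairwise_ising(halves3$train)),
                              halves3$test)
  expect_gt(kld_triplet, klds_pw[2])
})

test_that("fitted parameters correlate with the matching unit statistics", {
  set.seed(68)
  # heterogeneous independent rates: h tracks the logit rate monotonically
  p <- seq(0.05, 0.5, length.out = 6)
  r <- random_raster(6, 20000, p = p)
  fit <- fit_pairwise_ising(r)
  tab <- params_vs_statistics(list(fit), list(r))
  h_rows <- tab[tab$kind == "h", ]
  expect_gt(stats::cor(h_rows$parameter, h_rows$statistic, method = "spearman"),
            0.9)

  # equal rates: h spread collapses
  r_eq <- random_raster(5, 50000, p = rep(0.2, 5))
  fit_eq <- fit_pairwise_ising(r_eq)
  expect_lt(diff(range(fit_eq$params$h)), 0.2)

  # planted positive couplings show higher measured correlation than zero ones
  J <- matrix(0, 4, 4); J[1, 2] <- J[2, 1] <- 1.2
  params <- ising_params(rep(-1.5, 4), J)
  rs <- sample_ising(params, 30000, seed = 69)
  fit_j <- fit_pairwise_ising(rs)
  tab_j <- params_vs_statistics(list(fit_j), list(rs))
  j_rows <- tab_j[tab_j$kind == "J", ]
  coupled <- j_rows$i == 1 & j_rows$j == 2
  expect_gt(j_rows$statistic[coupled], max(j_rows$statistic[!coupled]))
})
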