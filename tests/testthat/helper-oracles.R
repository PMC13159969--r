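# Independent oracles used by the tests. These deliberately re-derive
# quantities from first principles (enumeration, closed forms, quadrature)
# without calling the package code paths they check.

# Boltzmann probabilities of a K-unit pairwise model by direct enumeration:
# explicit loop over all 2^K binary vectors, energies written out longhand.
oracle_ising_probs <- function(h, J) {
  K <- length(h)
  # expand.grid varies the first factor fastest, so row r is already the
  # binary expansion of r - 1 with unit 1 on the least significant bit
  words <- as.matrix(expand.grid(rep(list(0:1), K)))
  e <- numeric(nrow(words))
  for (r in seq_len(nrow(words))) {
    s <- words[r, ]
    acc <- sum(h * s)
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      acc <- acc + J[i, j] * s[i] * s[j]
    }
    e[r] <- acc
  }
  p <- exp(e)
  list(words = words, probs = p / sum(p))
}

# Orthant probability P(X1 > z1, X2 > z2) for standard bivariate normal with
# correlation rho, by 1-D quadrature over the conditional distribution.
oracle_orthant <- function(z1, z2, rho) {
  if (abs(rho) >= 1) {
    # degenerate: X2 = rho * X1
    return(if (rho > 0) stats::pnorm(max(z1, z2), lower.tail = FALSE)
           else stats::pnorm(z1, lower.tail = FALSE) -
                min(stats::pnorm(z1, lower.tail = FALSE), stats::pnorm(-z2)))
  }
  f <- function(x) {
    stats::dnorm(x) *
      stats::pnorm((z2 - rho * x) / sqrt(1 - rho^2), lower.tail = FALSE)
  }
  stats::integrate(f, z1, Inf, rel.tol = 1e-10)$value
}

# Binary correlation implied by dichotomizing a bivariate normal at
# thresholds giving marginal probabilities p1, p2 with latent correlation rho.
oracle_dg_correlation <- function(p1, p2, rho) {
  z1 <- stats::qnorm(1 - p1)
  z2 <- stats::qnorm(1 - p2)
  p11 <- oracle_orthant(z1, z2, rho)
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# Brunner-Munzel via the placement formulation (Brunner & Munzel 2000,
# eqs. written out directly), independent of the package's rank version.
oracle_brunner_munzel <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  # placements: P1[i] = #{y < x_i} + 0.5 #{y = x_i}, and vice versa
  P1 <- vapply(x, function(v) sum(y < v) + 0.5 * sum(y == v), 0)
  P2 <- vapply(y, function(v) sum(x < v) + 0.5 * sum(x == v), 0)
  p_hat <- mean(P2) / n1                  # estimate of P(X<Y) + P(X=Y)/2
  v1 <- stats::var(P1) / n2^2
  v2 <- stats::var(P2) / n1^2
  se <- sqrt(v1 / n1 + v2 / n2)
  stat <- (p_hat - 0.5) / se
  df <- (v1 / n1 + v2 / n2)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(statistic = stat, df = df,
       p_value = 2 * stats::pt(-abs(stat), df), relative_effect = p_hat)
}

# Exact Wilcoxon rank-sum p value by exhausting all group labelings.
oracle_wilcoxon_exact <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  n1 <- length(x)
  W_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  W_all <- apply(combs, 2, function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  })
  switch(alternative,
         less = mean(W_all <= W_obs),
         greater = mean(W_all >= W_obs),
         two.sided = min(1, 2 * min(mean(W_all <= W_obs), mean(W_all >= W_obs))))
}

# Entropy in bits straight from the definition, given a vector of outcomes.
oracle_entropy <- function(outcomes) {
  p <- table(outcomes) / length(outcomes)
  -sum(p * log2(p))
}

# random raster with given per-unit Bernoulli probabilities
random_raster <- function(K, n_bins, p = stats::runif(K, 0.05, 0.5)) {
  meapop:::new_raster(matrix(stats::rbinom(K * n_bins, 1, rep(p, n_bins)),
                             K, n_bins), 0.01)
}

# small synthetic voltage fixture with well-separated planted units;
# shared between the sorting unit tests and the acceptance suite
planted_recording <- function(duration_s = 60, noise_sd_uV = 8, seed = 5) {
  grid <- mea_grid(3, 300)
  tr <- generate_correlated_trains(c(3, 2, 2.5), diag(3), duration_s,
                                   seed = seed)
  pos <- data.frame(x_um = c(0, 600, 300), y_um = c(0, 0, 600))
  gt <- ground_truth(tr$trains, pos, duration_s)
  tmpl <- list(spike_template(100, recovery_frac = 0.2),
               spike_template(100, recovery_frac = 0.35),
               spike_template(100, recovery_frac = 0.5))
  rec <- synthesize_voltage(gt, tmpl, grid, noise_sd_uV = noise_sd_uV,
                            seed = seed + 1)
  list(recording = rec, truth = gt, grid = grid, templates = tmpl)
}
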