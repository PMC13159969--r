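#' Pairwise maximum-entropy (Ising) model parameters
#'
#' Container for the parameters of the second-order maximum-entropy model
#' over binary population words `s` in `{0,1}^K`,
#' `P(s) = exp(sum_i h_i s_i + sum_{i<j} J_ij s_i s_j) / Z`.
#' `h` collects the per-unit excitability terms and `J` the symmetric
#' pairwise interaction terms (zero diagonal). This is the distribution of
#' maximal entropy among all distributions matching a given set of unit
#' firing probabilities and pairwise co-activation probabilities.
#'
#' @param h numeric vector of length K.
#' @param J K x K numeric matrix, symmetric with zero diagonal. A scalar 0 is
#'   expanded to the all-zero matrix (independent units).
#' @return an object of class `ising_params`.
#' @export
ising_params <- function(h, J = 0) {
  h <- as.numeric(h)
  K <- length(h)
  if (length(J) == 1 && J == 0) J <- matrix(0, K, K)
  J <- as.matrix(J)
  if (!all(dim(J) == K)) stop("J must be K x K with K = length(h)")
  if (!isTRUE(all.equal(J, t(J), tolerance = 1e-10))) {
    stop("J must be symmetric")
  }
  if (any(abs(diag(J)) > 1e-12)) stop("J must have zero diagonal")
  if (!all(is.finite(h)) || !all(is.finite(J))) stop("parameters must be finite")
  structure(list(h = h, J = (J + t(J)) / 2, K = K), class = "ising_params")
}

#' @export
print.ising_params <- function(x, ...) {
  cat(sprintf("pairwise Ising parameters for K = %d units\n", x$K))
  cat("  h:", format(round(x$h, 3)), "\n")
  if (any(x$J != 0)) {
    cat(sprintf("  J: %d nonzero couplings, range [%.3f, %.3f]\n",
                sum(x$J[upper.tri(x$J)] != 0),
                min(x$J[upper.tri(x$J)]), max(x$J[upper.tri(x$J)])))
  } else {
    cat("  J: 0 (independent units)\n")
  }
  invisible(x)
}

#' Exact model word distribution
#'
#' Enumerates all `2^K` binary words and returns their exact Boltzmann
#' probabilities under a pairwise Ising model. Probabilities are strictly
#' positive and sum to one, so the model assigns finite surprise to every
#' possible population word -- the property that keeps held-out KL
#' divergences finite.
#'
#' @param params an [ising_params()] object with `K <= 16`.
#' @return numeric vector of length `2^K`; element `w + 1` is the probability
#'   of the word with integer code `w` (unit `i` on bit `i - 1`).
#' @examples
#' p <- model_word_distribution(ising_params(h = c(0, 0)))  # uniform on 4 words
#' @export
model_word_distribution <- function(params) {
  stopifnot(inherits(params, "ising_params"))
  if (params$K > 16) {
    stop("exact enumeration limited to K <= 16 (2^K states); got K = ", params$K)
  }
  S <- binary_states(params$K)
  # energy of each state: h . s + sum_{i<j} J_ij s_i s_j
  e <- S %*% params$h + rowSums((S %*% params$J) * S) / 2
  e <- e - max(e)                      # guard against overflow
  p <- exp(e)
  as.numeric(p / sum(p))
}

#' Split a raster into training and held-out halves
#'
#' Divides the time bins of a raster into two disjoint, exhaustive halves.
#' The default contiguous split (first half / second half) matches how
#' stationarity is assessed; an interleaved split (odd/even bins) is
#' available for non-stationary data.
#'
#' @param raster a `binarized_raster`.
#' @param method `"contiguous"` (default) or `"interleaved"`.
#' @return list with elements `train` and `test`, both rasters.
#' @export
split_train_test <- function(raster, method = c("contiguous", "interleaved")) {
  method <- match.arg(method)
  n <- ncol(raster)
  if (n < 2) stop("need at least 2 time bins to split")
  idx <- if (method == "contiguous") {
    seq_len(ceiling(n / 2))
  } else {
    seq(1, n, by = 2)
  }
  list(train = raster[, idx], test = raster[, -idx])
}

# empirical first and second moments of a raster: means p_i and
# co-activations p_ij = P(s_i = 1, s_j = 1) for i < j, as one vector
raster_moments <- function(raster) {
  K <- nrow(raster)
  n <- ncol(raster)
  m1 <- rowMeans(raster)
  cp <- tcrossprod(raster) / n
  ut <- upper.tri(cp)
  c(m1, cp[ut])
}

# sufficient-statistics design matrix: 2^K states x (K + K(K-1)/2) features
ising_design <- function(K) {
  S <- binary_states(K)
  P <- K * (K - 1) / 2
  M <- matrix(0, nrow(S), K + P)
  M[, seq_len(K)] <- S
  if (P > 0) {
    col <- K
    for (j in 2:K) for (i in seq_len(j - 1)) {
      col <- col + 1
      M[, col] <- S[, i] * S[, j]
    }
  }
  M
}

theta_to_params <- function(theta, K) {
  h <- theta[seq_len(K)]
  J <- matrix(0, K, K)
  if (K > 1) {
    J[upper.tri(J)] <- theta[-seq_len(K)]
    J <- J + t(J)
  }
  ising_params(h, J)
}

#' Fit the pairwise maximum-entropy model by exact enumeration
#'
#' Finds the Ising parameters `(h, J)` whose model distribution matches the
#' empirical unit firing probabilities and pairwise co-activation
#' probabilities of the training raster. The log-likelihood of this
#' exponential family is concave with gradient equal to the gap between
#' empirical and model moments, so a damped Newton ascent (exact Fisher
#' information from full `2^K` enumeration) converges to the unique maximum;
#' iteration stops once the largest moment residual falls below `tol`.
#'
#' Units that never (or always) fire in the training half have divergent
#' `h`; their empirical moments are clipped to `[1/(2n), 1 - 1/(2n)]` with a
#' warning, which keeps all parameters finite at a documented O(1/n) bias.
#'
#' @param raster training `binarized_raster` with `K <= 14` units.
#' @param tol convergence tolerance on the maximum absolute moment residual
#'   (default `1e-6`).
#' @param max_iter maximum Newton iterations (default 200; each iteration is
#'   one exact gradient/Hessian evaluation, far fewer than first-order
#'   ascent would need).
#' @return object of class `ising_fit`: `params`, `model_probs` (length
#'   `2^K`), `train_moments`, `model_moments`, `max_residual`, `converged`,
#'   `n_train`, `K`.
#' @seealso [evaluate_fit()], [model_word_distribution()]
#' @export
fit_pairwise_ising <- function(raster, tol = 1e-6, max_iter = 200) {
  K <- nrow(raster)
  n <- ncol(raster)
  if (K > 14) stop("exact fitting limited to K <= 14; got K = ", K)
  if (n < 2) stop("need at least 2 training bins")

  m_emp <- raster_moments(raster)
  means <- m_emp[seq_len(K)]
  if (any(means <= 0 | means >= 1)) {
    warning("unit(s) never or always active in training half; ",
            "moments clipped to [1/(2n), 1 - 1/(2n)]")
  }
  lo <- 1 / (2 * n)
  m_emp <- pmin(pmax(m_emp, lo), 1 - lo)

  M <- ising_design(K)
  theta <- c(stats::qlogis(m_emp[seq_len(K)]), rep(0, K * (K - 1) / 2))

  loglik <- function(theta) {
    e <- M %*% theta
    sum(theta * m_emp) - (max(e) + log(sum(exp(e - max(e)))))
  }
  model_moments <- function(theta) {
    e <- drop(M %*% theta)
    p <- exp(e - max(e)); p <- p / sum(p)
    list(p = p, m = drop(crossprod(M, p)))
  }

  ll <- loglik(theta)
  mm <- model_moments(theta)
  iter <- 0
  repeat {
    g <- m_emp - mm$m
    if (max(abs(g)) < tol || iter >= max_iter) break
    iter <- iter + 1
    # Fisher information = covariance of sufficient statistics under model
    Mp <- M * mm$p
    H <- crossprod(M, Mp) - tcrossprod(mm$m)
    step <- tryCatch(solve(H + diag(1e-10, ncol(M)), g),
                     error = function(e) g)   # gradient fallback
    lambda <- 1
    repeat {
      theta_new <- theta + lambda * step
      ll_new <- loglik(theta_new)
      if (ll_new >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    theta <- theta_new
    ll <- ll_new
    mm <- model_moments(theta)
  }

  max_res <- max(abs(m_emp - mm$m))
  if (max_res >= tol) {
    warning(sprintf(
      "maximum-entropy fit did not reach tol = %g after %d iterations (max moment residual %.3g)",
      tol, iter, max_res))
  }
  structure(list(params = theta_to_params(theta, K),
                 model_probs = mm$p,
                 train_moments = m_emp,
                 model_moments = mm$m,
                 max_residual = max_res,
                 converged = max_res < tol,
                 log_likelihood = ll,
                 n_train = n, K = K, iterations = iter),
            class = "ising_fit")
}

#' @export
print.ising_fit <- function(x, ...) {
  cat(sprintf("pairwise maximum-entropy fit: K = %d, %d training bins\n",
              x$K, x$n_train))
  cat(sprintf("  converged: %s (max moment residual %.2e, %d iterations)\n",
              x$converged, x$max_residual, x$iterations))
  invisible(x)
}

#' Empirical word distribution of a raster
#'
#' @param raster a `binarized_raster` with `K <= 16` units.
#' @return numeric vector of length `2^K` of empirical word frequencies
#'   (same word-integer indexing as [model_word_distribution()]).
#' @export
empirical_word_distribution <- function(raster) {
  K <- nrow(raster)
  stopifnot(K <= 16)
  w <- encode_words(raster)
  tabulate(w + 1L, 2L^K) / ncol(raster)
}

#' Held-out goodness of fit by KL divergence
#'
#' Computes `KL(empirical || model)` in bits between the empirical word
#' distribution of a held-out raster and a model word distribution. Because
#' the Ising model is strictly positive on all words the divergence is
#' always finite; larger values mean the pairwise model misses more of the
#' population structure (the headline complexity statistic).
#'
#' @param model_probs numeric vector of length `2^K` of model probabilities
#'   (e.g. `fit$model_probs` or [model_word_distribution()]).
#' @param test_raster held-out `binarized_raster` with matching K.
#' @return KL divergence in bits (non-negative scalar).
#' @export
evaluate_fit <- function(model_probs, test_raster) {
  if (inherits(model_probs, "ising_fit")) model_probs <- model_probs$model_probs
  K <- nrow(test_raster)
  if (length(model_probs) != 2^K) {
    stop("model distribution has ", length(model_probs),
         " words but test raster implies ", 2^K)
  }
  if (ncol(test_raster) == 0) stop("empty test half")
  kl_bits(empirical_word_distribution(test_raster), model_probs)
}

#' Fitted parameters versus empirical unit statistics
#'
#' Pairs every fitted excitability term `h_i` with the firing rate of its
#' unit and every interaction term `J_ij` with the Pearson correlation of
#' the corresponding binarized unit pair, across a collection of fits. The
#' long-format table supports the standard sanity check that excitability
#' increases with firing rate and interaction strength with pairwise
#' correlation.
#'
#' @param fits list of `ising_fit` objects.
#' @param rasters list of the training rasters the fits were computed from
#'   (same order and K).
#' @return data.frame with columns `fit`, `kind` (`"h"` or `"J"`), `i`, `j`
#'   (NA for `h` rows), `parameter`, `statistic` (firing rate in Hz for `h`,
#'   Pearson r for `J`).
#' @export
params_vs_statistics <- function(fits, rasters) {
  stopifnot(length(fits) == length(rasters), length(fits) >= 1)
  rows <- vector("list", length(fits))
  for (f in seq_along(fits)) {
    fit <- fits[[f]]
    raster <- rasters[[f]]
    stopifnot(nrow(raster) == fit$K)
    bin_s <- attr(raster, "bin_s")
    rate <- rowMeans(raster) / bin_s
    h_rows <- data.frame(fit = f, kind = "h", i = seq_len(fit$K), j = NA_integer_,
                         parameter = fit$params$h, statistic = rate)
    j_rows <- NULL
    if (fit$K > 1) {
      cm <- suppressWarnings(stats::cor(t(raster)))
      ut <- which(upper.tri(cm), arr.ind = TRUE)
      j_rows <- data.frame(fit = f, kind = "J",
                           i = ut[, 1], j = ut[, 2],
                           parameter = fit$params$J[ut],
                           statistic = cm[ut])
    }
    rows[[f]] <- rbind(h_rows, j_rows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
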