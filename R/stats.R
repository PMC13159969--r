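#' Brunner-Munzel rank test
#'
#' Two-sample rank test of the hypothesis of stochastic equality
#' `P(X < Y) + P(X = Y)/2 = 1/2`, robust to unequal variances and
#' non-normality. Uses midranks, the Brunner-Munzel variance estimator and
#' a t approximation with Satterthwaite-type degrees of freedom. Being
#' rank-based, the statistic and p value are invariant under any strictly
#' monotone transform applied to both samples.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternatives on the relative effect `P(X < Y) + P(X = Y)/2` vs 1/2).
#' @return list of class `group_comparison`: `statistic`, `df`, `p_value`,
#'   `relative_effect`, `n_x`, `n_y`, `test`.
#' @references Brunner, E. and Munzel, U. (2000) The nonparametric
#'   Behrens-Fisher problem: asymptotic theory and a small-sample
#'   approximation. Biometrical Journal 42, 17-25.
#' @export
brunner_munzel <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  N <- n1 + n2
  r <- rank(c(x, y))                 # midranks in the combined sample
  r1 <- r[seq_len(n1)]; r2 <- r[-seq_len(n1)]
  R1 <- mean(r1); R2 <- mean(r2)
  p_hat <- (R2 - (n2 + 1) / 2) / n1  # relative effect P(X<Y) + P(X=Y)/2

  ri1 <- rank(x); ri2 <- rank(y)     # within-sample midranks
  S1 <- sum((r1 - ri1 - R1 + (n1 + 1) / 2)^2) / (n1 - 1)
  S2 <- sum((r2 - ri2 - R2 + (n2 + 1) / 2)^2) / (n2 - 1)
  if (S1 == 0 && S2 == 0) {
    # two degenerate regimes: everything tied (no evidence) vs complete
    # separation (maximal evidence, variance estimator vanishes)
    if (p_hat == 0.5) {
      warning("degenerate variance (all values tied): p = 1")
      stat <- 0; p <- 1
    } else {
      warning("samples are completely separated: variance estimate is zero, ",
              "p value reported as 0")
      stat <- sign(p_hat - 0.5) * Inf
      p <- switch(alternative,
                  two.sided = 0,
                  greater = if (p_hat > 0.5) 0 else 1,
                  less = if (p_hat < 0.5) 0 else 1)
    }
    res <- list(statistic = stat, df = NA_real_, p_value = p,
                relative_effect = p_hat, n_x = n1, n_y = n2,
                test = "Brunner-Munzel")
    class(res) <- "group_comparison"
    return(res)
  }
  sig <- n1 * S1 + n2 * S2
  stat <- n1 * n2 * (R2 - R1) / (N * sqrt(sig))
  df <- sig^2 / ((n1 * S1)^2 / (n1 - 1) + (n2 * S2)^2 / (n2 - 1))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(stat), df),
              greater = stats::pt(stat, df, lower.tail = FALSE),
              less = stats::pt(stat, df))
  structure(list(statistic = stat, df = df, p_value = p,
                 relative_effect = p_hat, n_x = n1, n_y = n2,
                 test = "Brunner-Munzel"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4f, p = %.4g (n = %d, %d)\n",
              x$test, x$statistic, x$p_value, x$n_x, x$n_y))
  if (!is.null(x$relative_effect)) {
    cat(sprintf("  relative effect P(X<Y) + P(X=Y)/2 = %.4f\n", x$relative_effect))
  }
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_comparisons number of pairwise comparisons performed. This is a
#'   required argument: it is never inferred from the data.
#' @param alpha family-wise significance level (default 0.05).
#' @return corrected per-comparison threshold `alpha / n_comparisons`.
#' @examples
#' bonferroni_alpha(15)   # 0.00333...
#' @export
bonferroni_alpha <- function(n_comparisons, alpha = 0.05) {
  stopifnot(is_count(n_comparisons), alpha > 0, alpha < 1)
  alpha / n_comparisons
}

#' Normality and variance-homogeneity screening
#'
#' Screens a set of samples the way the downstream test choice requires:
#' per-group Kolmogorov-Smirnov test against a normal with the sample's
#' moments, and Levene's test of variance homogeneity across groups using
#' absolute deviations from the group means. When any group departs from
#' normality or variances differ, a rank test robust to both
#' (Brunner-Munzel) is indicated.
#'
#' @param samples named list of numeric vectors (>= 5 values each).
#' @param alpha significance level for the flags (default 0.05).
#' @return list: `normality` data.frame (`group`, `ks_p`, `normal`),
#'   `levene_p`, `equal_variances`, `recommend_rank_test`.
#' @export
distribution_checks <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), all(lengths(samples) >= 5))
  ids <- names(samples) %||% paste0("g", seq_along(samples))
  ks_p <- vapply(samples, function(x) {
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  }, 0)
  normality <- data.frame(group = ids, ks_p = ks_p, normal = ks_p >= alpha)
  rownames(normality) <- NULL
  levene_p <- NA_real_
  if (length(samples) >= 2) {
    y <- unlist(samples, use.names = FALSE)
    g <- factor(rep(ids, lengths(samples)))
    levene_p <- car::leveneTest(y, g, center = mean)[1, "Pr(>F)"]
  }
  list(normality = normality,
       levene_p = levene_p,
       equal_variances = is.na(levene_p) || levene_p >= alpha,
       recommend_rank_test = any(!normality$normal) ||
         (!is.na(levene_p) && levene_p < alpha))
}

#' Wilcoxon rank-sum test
#'
#' Thin wrapper around [stats::wilcox.test()] (exact for small samples
#' without ties, normal approximation with tie correction otherwise),
#' returned in the package's group-comparison shape.
#'
#' @param x,y numeric samples.
#' @param alternative passed to [stats::wilcox.test()].
#' @return list of class `group_comparison`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative))
  structure(list(statistic = unname(wt$statistic), df = NA_real_,
                 p_value = wt$p.value, relative_effect = NULL,
                 n_x = length(x), n_y = length(y),
                 test = "Wilcoxon rank sum"),
            class = "group_comparison")
}

#' All-pairs group comparison table
#'
#' Runs a two-sample test on every pair of groups and reports each p value
#' against the Bonferroni-corrected threshold for the stated number of
#' comparisons.
#'
#' @param samples named list of numeric vectors, one per group.
#' @param test `"brunner_munzel"` (default) or `"wilcoxon"`.
#' @param n_comparisons number of comparisons for the Bonferroni
#'   correction; defaults to the number of pairs tested here, but should be
#'   set explicitly when these pairs are part of a larger family.
#' @param alpha family-wise level (default 0.05).
#' @return data.frame: `group_a`, `group_b`, `test`, `statistic`, `p_value`,
#'   `corrected_alpha`, `significant`.
#' @export
compare_groups <- function(samples, test = c("brunner_munzel", "wilcoxon"),
                           n_comparisons = NULL, alpha = 0.05) {
  test <- match.arg(test)
  ids <- names(samples) %||% paste0("g", seq_along(samples))
  pairs <- utils::combn(length(samples), 2)
  n_comparisons <- n_comparisons %||% ncol(pairs)
  thr <- bonferroni_alpha(n_comparisons, alpha)
  fun <- if (test == "brunner_munzel") brunner_munzel else wilcoxon_rank_sum
  rows <- apply(pairs, 2, function(ij) {
    res <- fun(samples[[ij[1]]], samples[[ij[2]]])
    data.frame(group_a = ids[ij[1]], group_b = ids[ij[2]], test = res$test,
               statistic = res$statistic, p_value = res$p_value,
               corrected_alpha = thr, significant = res$p_value < thr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
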