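#' Shapiro-Wilk normality gate
#'
#' Decides whether a sample is treated as normally distributed for the purpose
#' of choosing between a t test and its rank-based alternative. The gate is
#' the Shapiro-Wilk test: the sample is treated as normal when the
#' Shapiro-Wilk p-value is at least `alpha` (i.e. normality is not rejected).
#' Some study protocols phrase the gate in the opposite direction; the
#' `invert` escape hatch flips the decision for such replication work.
#'
#' @param x numeric vector.
#' @param alpha significance level of the Shapiro-Wilk test (default 0.05).
#' @param invert if `TRUE`, return the opposite decision (treat as normal
#'   when Shapiro-Wilk rejects). Provided only to replicate analyses that
#'   state the gate in inverted form; leave `FALSE` for conventional use.
#' @return `TRUE` if the sample is to be treated as normal. Samples with
#'   fewer than 3 values or zero variance return `FALSE` (rank-based
#'   fallback).
#' @export
normality_gate <- function(x, alpha = 0.05, invert = FALSE) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || near_constant(x)) return(FALSE)
  sw <- stats::shapiro.test(x)
  normal <- sw$p.value >= alpha
  if (invert) !normal else normal
}

# variance indistinguishable from floating-point noise at the sample's scale
near_constant <- function(x) {
  diff(range(x)) <= 1e-10 * max(abs(x), 1)
}

# Common container for test results.
av_test_result <- function(statistic, p_value, test_name, n) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 test_name = test_name, n = n),
            class = "av_test")
}

#' @export
print.av_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g, n = %d\n",
              x$test_name, x$statistic, x$p_value, x$n))
  invisible(x)
}

# Exact-when-possible one-sample Wilcoxon signed-rank vs mu.
# Zeros (x == mu) are dropped by convention; exact distribution is used up to
# n_exact nonzero values when the absolute deviations are tie-free.
signed_rank_test <- function(x, mu = 0, n_exact = 25L) {
  d <- x - mu
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(av_test_result(0, 1, "wilcoxon_signed_rank", 0L))
  use_exact <- n <= n_exact && !anyDuplicated(abs(d))
  wt <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = use_exact,
                                            correct = !use_exact))
  av_test_result(wt$statistic, wt$p.value, "wilcoxon_signed_rank", n)
}

#' One-sample location test with normality gate
#'
#' Tests whether the location of `x` differs from `mu`. A Shapiro-Wilk gate
#' selects the one-sample t test when the sample looks normal, and the
#' one-sample Wilcoxon signed-rank test (exact for small samples) otherwise.
#' This is the dispatch used to call per-organ metabolite release/uptake from
#' per-animal log2(V/A) values.
#'
#' @param x numeric vector (n >= 3 for a meaningful test).
#' @param mu null location (default 0).
#' @param normality_alpha Shapiro-Wilk level for the gate.
#' @param invert_gate see [normality_gate()].
#' @return an `av_test` list: `statistic`, `p_value`, `test_name`
#'   (`"one_sample_t"` or `"wilcoxon_signed_rank"`), `n`.
#' @export
one_sample_location_test <- function(x, mu = 0, normality_alpha = 0.05,
                                     invert_gate = FALSE) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(av_test_result(NA_real_, NA_real_, "none", 0L))
  if (near_constant(x)) {
    # (numerically) constant sample: all equal to mu means no shift (p = 1);
    # constant off the null is handled exactly by the signed-rank test
    if (abs(mean(x) - mu) <= 1e-10 * max(abs(mu), 1))
      return(av_test_result(0, 1, "one_sample_t", n))
    return(signed_rank_test(x, mu))
  }
  if (n >= 3L && normality_gate(x, normality_alpha, invert_gate)) {
    tt <- stats::t.test(x, mu = mu)
    av_test_result(tt$statistic, tt$p.value, "one_sample_t", n)
  } else {
    signed_rank_test(x, mu)
  }
}

#' Paired two-group test with normality gate
#'
#' Compares paired observations (e.g. littermate WT/CF pairs). The gate is
#' applied to the paired differences: paired t test when they look normal,
#' Wilcoxon signed-rank on the differences otherwise (exact for small n).
#'
#' @param x,y numeric vectors of equal length, paired by position.
#' @param normality_alpha,invert_gate gate parameters, see [normality_gate()].
#' @return an `av_test` list; `n` is the number of complete pairs.
#' @export
paired_two_group_test <- function(x, y, normality_alpha = 0.05,
                                  invert_gate = FALSE) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  d <- x[keep] - y[keep]
  n <- length(d)
  if (n == 0L) return(av_test_result(NA_real_, NA_real_, "none", 0L))
  if (all(abs(d) <= 1e-10 * max(abs(c(x, y)), 1)))
    return(av_test_result(0, 1, "paired_t", n))
  if (near_constant(d)) return(signed_rank_test(d, 0))
  if (normality_gate(d, normality_alpha, invert_gate)) {
    tt <- stats::t.test(x[keep], y[keep], paired = TRUE)
    av_test_result(tt$statistic, tt$p.value, "paired_t", n)
  } else {
    res <- signed_rank_test(d, 0)
    res$n <- n
    res
  }
}

#' Unpaired two-group test with normality gate
#'
#' Student's two-sample t test when both groups pass the Shapiro-Wilk gate,
#' Mann-Whitney U (rank-sum) test otherwise. Used for genotype contrasts of
#' unpaired quantities such as urine/artery reabsorption ratios.
#'
#' @param x,y numeric vectors (independent groups).
#' @param normality_alpha,invert_gate gate parameters, see [normality_gate()].
#' @return an `av_test` list; `n` is the total number of values used.
#' @export
two_group_test <- function(x, y, normality_alpha = 0.05, invert_gate = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n <- length(x) + length(y)
  if (length(x) == 0L || length(y) == 0L)
    return(av_test_result(NA_real_, NA_real_, "none", n))
  if (near_constant(c(x, y))) return(av_test_result(0, 1, "student_t", n))
  normal <- normality_gate(x, normality_alpha, invert_gate) &&
    normality_gate(y, normality_alpha, invert_gate)
  if (normal) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    av_test_result(tt$statistic, tt$p.value, "student_t", n)
  } else {
    use_exact <- length(x) <= 25L && length(y) <= 25L &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                              correct = !use_exact))
    av_test_result(wt$statistic, wt$p.value, "mann_whitney_u", n)
  }
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment. `NA` p-values propagate as `NA`
#' and are not counted in the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Mean +/- k SD outlier removal
#'
#' Drops values lying more than `k` sample standard deviations from the
#' sample mean, with mean and SD computed once from the full input (single
#' pass, no re-screening). A zero-variance input is returned unchanged.
#'
#' @param x numeric vector (n >= 3 recommended).
#' @param k SD multiple defining the retention boundary (default 2.5).
#' @return the retained values, in their original order.
#' @export
remove_outliers <- function(x, k = 2.5) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(x)
  s <- stats::sd(x)
  if (s == 0) return(x)
  x[abs(x - mean(x)) <= k * s]
}

#' Spearman rank correlation with significance test
#'
#' Rank-based correlation with a two-sided p-value (exact permutation null
#' for n < 10 without ties, t approximation otherwise; ties handled by
#' average ranks).
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @return list with `rho`, `p_value`, `n`, and `flagged` (`TRUE` when rho is
#'   undefined because one variable has zero rank variance).
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L || stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, flagged = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n, flagged = FALSE)
}
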