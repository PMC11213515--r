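# Independent brute-force oracles used to verify the statistical primitives.

# Exact one-sample signed-rank two-sided p by exhaustive enumeration of all
# 2^n sign assignments (no ties, no zeros assumed).
signed_rank_enum_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# BH step-up q-values straight from the definition:
# q_i = min over j with p_j >= p_i of m * p_j / rank(p_j), capped at 1.
bh_enum_q <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i])
    min(1, min(m * p[js] / r[js]))
  }, numeric(1))
}

# Spearman rho from the textbook d^2 formula (tie-free inputs).
spearman_enum_rho <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
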