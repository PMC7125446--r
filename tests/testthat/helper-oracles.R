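# Independent oracles used to freeze expected values. None of these call the
# package's implementation paths.

# Supremum distance between two empirical distribution functions, by direct
# evaluation at every observed point.
edf_sup_distance <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), 0)
  fy <- vapply(pts, function(t) mean(y <= t), 0)
  max(abs(fx - fy))
}

# Exact two-sided Mann-Whitney p-value by full enumeration of the
# choose(n + m, n) assignments of the pooled ranks to the first sample.
mw_enum_p <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- combn(length(pooled), n)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# Upper-tail hypergeometric probability by enumerating every size-n draw
# from a universe of N with K successes.
hyper_enum_p <- function(N, K, n, k) {
  draws <- combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}

# Spearman coefficient via the rank transform + product-moment formula.
rank_pearson <- function(x, y) {
  cor(rank(x), rank(y), method = "pearson")
}

# Degree profile with prescribed per-gene degree matrices, for exercising
# score/separability arithmetic directly.
make_profile <- function(deg_c, deg_e, thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- seq_len(ncol(deg_c)) / 10
  ids <- sprintf("g%02d", seq_len(nrow(deg_c)))
  mdgnet:::new_degree_profile(ids, thresholds, deg_c, deg_e)
}

# Small deterministic expression fixture: n_genes x n_samples matrix of
# jittered values with no ties.
fixture_expr <- function(n_genes, n_samples, seed = 1) {
  withr::with_seed(seed, {
    expr_table(matrix(rnorm(n_genes * n_samples), n_genes))
  })
}
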