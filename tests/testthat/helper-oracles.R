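# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# Brute-force two-sample KS statistic: sweep every candidate breakpoint of
# the pooled support and take the largest ECDF gap.
ks_oracle_D <- function(a, b) {
  breaks <- sort(unique(c(a, b)))
  max(vapply(breaks, function(x) abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

# Two-pass coefficient of variation: explicit mean, then explicit sum of
# squared deviations with the n-1 denominator.
cov_oracle <- function(v) {
  n <- length(v)
  mu <- sum(v) / n
  ss <- 0
  for (x in v) ss <- ss + (x - mu)^2
  sqrt(ss / (n - 1)) / mu
}

# Exact bootstrap sd of the COV for tiny n: enumerate all n^n equally
# likely resample index tuples.
bootstrap_cov_sd_oracle <- function(v) {
  n <- length(v)
  idx <- expand.grid(rep(list(seq_len(n)), n))
  covs <- apply(idx, 1, function(ii) {
    r <- v[ii]
    stats::sd(r) / mean(r)
  })
  sqrt(mean((covs - mean(covs))^2))   # population sd over the exact distribution
}

# All samples of a given size over a small value alphabet (order ignored:
# multisets, since the KS statistic is order-invariant).
all_multisets <- function(alphabet, size) {
  grids <- expand.grid(rep(list(alphabet), size))
  keys <- apply(grids, 1, function(r) paste(sort(r), collapse = ","))
  grids[!duplicated(keys), , drop = FALSE]
}

# Small well-separated two-cloud matrix for clustering tests.
two_cloud_matrix <- function(n_per = 40, gap = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2), ncol = 2),
             matrix(rnorm(n_per * 2, mean = gap), ncol = 2))
  rownames(x) <- sprintf("c%02d", seq_len(2 * n_per))
  colnames(x) <- c("g1", "g2")
  x
}

# Access the package's internal metric distance computation for direct checks.
metric_dist_for_test <- function(x, centroids, name = "euclidean", order = NULL) {
  ctfingerprint:::metric_distances(x, centroids,
                                   ctfingerprint::distance_metric(name, order))
}
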