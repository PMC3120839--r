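test_that("simulation is seed-deterministic and respects degenerate limits", {
  genes <- stats::setNames(c(20, 24), c("gA", "gB"))
  spec <- population_spec(50, subpop_spec(1, genes, 1e-9), seed = 11)
  s1 <- simulate_cells(spec)
  s2 <- simulate_cells(spec)
  expect_identical(s1$ct$values, s2$ct$values)
  expect_identical(s1$labels, s2$labels)
  # vanishing sd, no dropout: every cell shares one Ct vector
  expect_lt(max(abs(sweep(s1$ct$values, 2, c(20, 24)))), 1e-6)

  # dropout probability 1 pins the whole column at the floor
  spec2 <- population_spec(30, subpop_spec(1, genes, 1, dropout_probs = c(0, 1)),
                           seed = 3)
  s3 <- simulate_cells(spec2)
  expect_true(all(s3$ct$values[, "gB"] == 40))
  expect_true(all(s3$ct$values[, "gA"] < 40))
})

test_that("mixture weights are validated and realised within multinomial bounds", {
  genes <- stats::setNames(c(20, 24), c("gA", "gB"))
  expect_error(population_spec(10, list(subpop_spec(0.6, genes, 1),
                                        subpop_spec(0.6, genes, 1))),
               "sum to 1")
  subs <- lapply(1:3, function(i) subpop_spec(1 / 3, genes + i, 1))
  counts <- table(simulate_cells(population_spec(300, subs, seed = 5))$labels)
  bounds <- stats::qbinom(c(0.005, 0.995), 300, 1 / 3)
  expect_true(all(counts >= bounds[1] & counts <= bounds[2]))
})

test_that("large-sample moments converge to the specification", {
  genes <- stats::setNames(c(18, 26), c("hi", "lo"))
  spec <- population_spec(10000, subpop_spec(1, genes, c(0.8, 1.4)), seed = 21)
  v <- simulate_cells(spec)$ct$values
  for (j in 1:2) {
    se_mean <- c(0.8, 1.4)[j] / sqrt(10000)
    expect_lt(abs(mean(v[, j]) - genes[j]), 3 * se_mean)
    se_sd <- c(0.8, 1.4)[j] / sqrt(2 * 9999)
    expect_lt(abs(stats::sd(v[, j]) - c(0.8, 1.4)[j]), 3 * se_sd)
  }
})

test_that("a homogeneous Gaussian population passes a KS check in most seeds", {
  # type-I calibration of the generator: one subpopulation, no bursts, no
  # dropout; the per-gene KS test against the generating law should be
  # non-significant at alpha = 0.01 in at least 95% of seeds
  genes <- stats::setNames(22, "g")
  rejections <- vapply(1:60, function(s) {
    v <- simulate_cells(population_spec(200, subpop_spec(1, genes, 1.2), seed = s))$ct$values[, 1]
    suppressWarnings(stats::ks.test(v, "pnorm", 22, 1.2)$p.value) < 0.01
  }, logical(1))
  expect_gte(mean(!rejections), 0.95)
})

test_that("burst genes are left-skewed in Ct (excess mRNA)", {
  genes <- stats::setNames(c(22, 22), c("burst", "calm"))
  spec <- population_spec(5000, subpop_spec(1, genes, 1, burst_genes = "burst"),
                          seed = 8)
  v <- simulate_cells(spec)$ct$values
  skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  expect_lt(skew(v[, "burst"]), -0.5)
  expect_lt(abs(skew(v[, "calm"])), 0.3)
})

test_that("the study fixture has the advertised structure", {
  fx <- make_study_fixture(seed = 13)
  fx2 <- make_study_fixture(seed = 13)
  expect_identical(fx$cd34lo$values, fx2$cd34lo$values)
  expect_identical(fx$sp$values, fx2$sp$values)

  # signal genes carry between-archetype variance, noise genes do not:
  # compare the variance of archetype-conditional means per gene
  v <- fx$cd34lo$values
  lab <- fx$labels$cd34lo
  between_var <- apply(v, 2, function(col) stats::var(tapply(col, lab, mean)))
  noise_genes <- setdiff(fx$cd34lo$gene_ids, fx$signal_genes)
  expect_gt(min(between_var[fx$signal_genes]), max(between_var[noise_genes]))

  # cd34hi archetype-1 count is near the 0.04 weight expectation (12/300)
  n1 <- sum(fx$labels$cd34hi == 1)
  bounds <- stats::qbinom(c(0.0005, 0.9995), 300, 0.04)
  expect_gte(n1, bounds[1])
  expect_lte(n1, bounds[2])

  # relative variability falls with expression: on the linear mRNA scale
  # (2^-Ct), genes detected later (higher Ct, less mRNA) have larger COV
  gauss <- setdiff(noise_genes, c("g20", "g27", "g35"))
  covs_linear <- apply(2^(-v[, gauss]), 2, function(col) stats::sd(col) / mean(col))
  means_ct <- colMeans(v[, gauss])
  expect_gt(stats::cor(means_ct, covs_linear, method = "spearman"), 0.5)
})
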