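test_that("the degenerate k = 1 fit is the coordinate-wise mean", {
  x <- two_cloud_matrix(n_per = 10)
  fit <- fcm_fit(x, k = 1, m = 2, seed = 1)
  expect_equal(unname(fit$centroids[1, ]), unname(colMeans(x)))
  expect_true(all(fit$memberships == 1))
  d2 <- rowSums(sweep(x, 2, colMeans(x))^2)
  expect_equal(fit$objective, sum(d2))
})

test_that("memberships are row-stochastic and separated clouds are resolved", {
  x <- two_cloud_matrix()
  fit <- fcm_fit(x, k = 2, m = 1.5, n_restarts = 5, seed = 2)
  expect_true(fit$converged)
  expect_equal(unname(rowSums(fit$memberships)), rep(1, nrow(x)), tolerance = 1e-9)
  expect_true(all(apply(fit$memberships, 1, max) > 0.99))
  # the two hard groups match the generating clouds
  truth <- rep(1:2, each = 40)
  expect_equal(partition_agreement(hard_assignment(fit), truth), 1)
})

test_that("input validation and determinism hold", {
  x <- two_cloud_matrix(n_per = 5)
  expect_error(fcm_fit(x, k = 11), "cannot exceed")
  expect_error(fcm_fit(x, k = 2, m = 1), "> 1")
  f1 <- fcm_fit(x, k = 2, m = 2, n_restarts = 3, seed = 7)
  f2 <- fcm_fit(x, k = 2, m = 2, n_restarts = 3, seed = 7)
  expect_identical(f1$memberships, f2$memberships)
  expect_identical(f1$centroids, f2$centroids)
})

test_that("cell-wise duplication leaves the partition unchanged", {
  x <- two_cloud_matrix(n_per = 25, seed = 4)
  fit1 <- fcm_fit(x, k = 2, m = 1.8, n_restarts = 5, seed = 3)
  xx <- rbind(x, x)
  rownames(xx) <- c(paste0(rownames(x), "_a"), paste0(rownames(x), "_b"))
  fit2 <- fcm_fit(xx, k = 2, m = 1.8, n_restarts = 5, seed = 8)
  # match centroids by proximity, then compare
  d <- metric_dist_for_test(fit1$centroids, fit2$centroids)
  perm <- apply(d, 1, which.min)
  expect_true(all(sort(perm) == 1:2))
  expect_equal(unname(fit2$centroids[perm, ]), unname(fit1$centroids),
               tolerance = 1e-4)
  expect_equal(unname(fit2$memberships[seq_len(nrow(x)), perm]),
               unname(fit1$memberships), tolerance = 1e-4)
  expect_equal(unname(fit2$memberships[nrow(x) + seq_len(nrow(x)), perm]),
               unname(fit1$memberships), tolerance = 1e-4)
})

test_that("cell-order permutation recovers the same partition", {
  fx <- make_separated_fixture(seed = 21)
  e <- normalize_ct(fx$ct)
  fit <- fcm_fit(e, k = 3, m = 1.5, n_restarts = 5, seed = 1)
  perm <- sample(seq_along(fx$labels))
  fitp <- fcm_fit(e$values[perm, ], k = 3, m = 1.5, n_restarts = 5, seed = 2)
  expect_equal(partition_agreement(hard_assignment(fit)[perm],
                                   hard_assignment(fitp)), 1)
})

test_that("k-means at k = n has objective 0 and the FCM m -> 1 limit matches it", {
  x <- two_cloud_matrix(n_per = 4, seed = 6)
  km_all <- kmeans_fit(x, k = nrow(x), seed = 1)
  expect_equal(km_all$objective, 0)

  fx <- make_separated_fixture(seed = 9)
  e <- normalize_ct(fx$ct)
  km <- kmeans_fit(e, 3, seed = 5)
  expect_equal(partition_agreement(hard_assignment(km), fx$labels), 1,
               tolerance = 0.05)
  hardened <- fcm_fit(e, 3, m = 1.01, n_restarts = 5, seed = 5)
  expect_gte(partition_agreement(hardened, km), 0.99)
})

test_that("FCM agrees with an independent fuzzy c-means implementation", {
  skip_if_not_installed("e1071")
  fx <- make_separated_fixture(seed = 14)
  e <- normalize_ct(fx$ct)
  ours <- fcm_fit(e, 3, m = 2, n_restarts = 5, seed = 1)
  set.seed(1)
  theirs <- e1071::cmeans(e$values, centers = 3, m = 2, iter.max = 300)
  expect_gte(partition_agreement(hard_assignment(ours),
                                 as.integer(theirs$cluster)), 0.99)
  # matched centroids of the two optima coincide
  d <- metric_dist_for_test(ours$centroids, theirs$centers)
  perm <- apply(d, 1, which.min)
  expect_true(all(sort(perm) == 1:3))
  expect_equal(unname(theirs$centers[perm, ]), unname(ours$centroids),
               tolerance = 1e-3)
})

test_that("projection reproduces training occupancy and the coincidence rule", {
  fx <- make_separated_fixture(seed = 10)
  e <- normalize_ct(fx$ct)
  fit <- fcm_fit(e, 3, m = 1.5, n_restarts = 5, seed = 4)
  proj <- project_population(fit, e)
  train_occ <- tabulate(hard_assignment(fit), 3) / nrow(e$values)
  expect_equal(unname(proj$occupancy$fractions), train_occ)
  expect_equal(proj$memberships, fit$memberships, tolerance = 1e-6)

  # a cell exactly at centroid 2 gets membership (0, 1, 0)
  probe <- rbind(fit$centroids[2, ])
  rownames(probe) <- "at_centroid"
  u <- project_population(fit, probe)$memberships
  expect_equal(unname(u[1, ]), c(0, 1, 0))

  expect_error(project_population(fit, e$values[, 1:3]), "lacks genes")
})

test_that("partition agreement is permutation-invariant with a null near zero", {
  lab <- rep(1:3, each = 20)
  expect_equal(partition_agreement(lab, lab), 1)
  relab <- c(2, 3, 1)[lab]
  expect_equal(partition_agreement(lab, relab), 1)
  expect_error(partition_agreement(lab, lab[-1]), "different cells")

  set.seed(88)
  null_small <- replicate(20, {
    a <- sample(1:3, 300, replace = TRUE)
    b <- sample(1:3, 300, replace = TRUE)
    abs(partition_agreement(a, b))
  })
  expect_gte(mean(null_small < 0.05), 0.95)
})

test_that("distance metrics reduce to one another at matching orders", {
  x <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
  cen <- matrix(c(0, 0), 1, 2)
  expect_equal(metric_dist_for_test(x, cen)[2, 1], 5)                      # euclidean
  expect_equal(metric_dist_for_test(x, cen, "manhattan")[2, 1], 7)
  expect_equal(metric_dist_for_test(x, cen, "minkowski", 2)[2, 1], 5)
  expect_equal(metric_dist_for_test(x, cen, "minkowski", 1)[2, 1], 7)
  expect_error(distance_metric("minkowski"), "requires an order")
  expect_error(distance_metric("minkowski", 0.5), ">= 1")
})
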