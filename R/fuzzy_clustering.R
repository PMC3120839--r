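# Fuzzy c-means clustering with pluggable distance metrics, hard k-means,
# and projection of new populations onto fixed centroids.

#' Distance metric specification
#'
#' @param name One of `"euclidean"`, `"manhattan"`, `"minkowski"`.
#' @param order Minkowski order `p >= 1`; euclidean is `p = 2`, manhattan
#'   `p = 1`.
#' @return An object of class `distance_metric`.
#' @export
distance_metric <- function(name = c("euclidean", "manhattan", "minkowski"),
                            order = NULL) {
  name <- match.arg(name)
  p <- switch(name, euclidean = 2, manhattan = 1, minkowski = order)
  if (is.null(p)) stop("minkowski metric requires an order")
  if (p < 1) stop("minkowski order must be >= 1")
  structure(list(name = name, order = p), class = "distance_metric")
}

# cells x k matrix of distances from rows of x to rows of centroids
metric_distances <- function(x, centroids, metric) {
  p <- metric$order
  k <- nrow(centroids)
  d <- matrix(0, nrow(x), k)
  for (j in seq_len(k)) {
    diff <- abs(sweep(x, 2, centroids[j, ], "-"))
    d[, j] <- if (p == 2) sqrt(rowSums(diff * diff))
              else if (p == 1) rowSums(diff)
              else rowSums(diff^p)^(1 / p)
  }
  d
}

# FCM membership update for given distances; handles centroid-coincident
# cells (d = 0 -> full membership there).
fcm_memberships <- function(d, m) {
  k <- ncol(d)
  if (k == 1) return(matrix(1, nrow(d), 1))
  zero <- d < .Machine$double.eps
  has_zero <- rowSums(zero) > 0
  expo <- 2 / (m - 1)
  # ratios are taken to the row-minimum distance so every term lies in
  # [0, 1]: small fuzziness (large exponents) can then only underflow,
  # never overflow to Inf/NaN
  dmin <- do.call(pmin, as.data.frame(d))
  ratio <- (dmin / pmax(d, .Machine$double.xmin))^expo
  u <- ratio / rowSums(ratio)
  if (any(has_zero)) {
    u[has_zero, ] <- 0
    u[has_zero, ] <- zero[has_zero, , drop = FALSE] /
      rowSums(zero[has_zero, , drop = FALSE])
  }
  u
}

# k-means++-style seeding: first seed cell uniform, then sample cells with
# probability proportional to squared distance from the nearest seed.  The
# returned centroids are pulled 5% toward the global mean so no centroid
# coincides exactly with a data point (which would be an absorbing state
# under the full-membership rule for coincident cells).
init_centroids <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, x[idx[1], ], "-")^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[j] <- sample.int(n, 1, prob = prob)
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j], ], "-")^2))
    }
  }
  seeds <- x[idx, , drop = FALSE]
  centre <- colMeans(x)
  0.95 * seeds + 0.05 * matrix(centre, k, ncol(x), byrow = TRUE)
}

new_cluster_model <- function(centroids, memberships, m, k, metric, objective,
                              n_iter, converged, seed, cell_ids) {
  rownames(memberships) <- cell_ids
  colnames(memberships) <- rownames(centroids) <- paste0("cluster", seq_len(k))
  structure(list(centroids = centroids, memberships = memberships, m = m,
                 k = k, metric = metric, objective = objective,
                 n_iter = n_iter, converged = converged, seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, m = %g, metric = %s (p = %g)\n",
              x$k, x$m, x$metric$name, x$metric$order))
  cat(sprintf("  %d cells; objective %.6g after %d iterations (%s)\n",
              nrow(x$memberships), x$objective, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

fcm_single_run <- function(x, k, m, metric, tol, max_iter) {
  centroids <- init_centroids(x, k)
  obj_prev <- Inf
  u <- NULL
  for (it in seq_len(max_iter)) {
    d <- metric_distances(x, centroids, metric)
    u_new <- fcm_memberships(d, m)
    obj <- sum(u_new^m * d^2)
    du <- if (is.null(u)) Inf else max(abs(u_new - u))
    u <- u_new
    # weighted-mean centroid update (generalised FCM: retained for all metrics)
    um <- u^m
    centroids <- t(um) %*% x / colSums(um)
    rel <- if (is.finite(obj_prev)) abs(obj_prev - obj) / max(obj_prev, .Machine$double.eps) else Inf
    # descent is guaranteed only for the Euclidean objective; the weighted-mean
    # centroid update is an approximation for other metrics
    if (metric$order == 2 && obj > obj_prev + 1e-8 * max(1, obj_prev))
      warning("FCM objective increased; numerical instability")
    obj_prev <- obj
    if (rel < tol || du < tol)
      return(fcm_finalize(x, centroids, m, metric, it, TRUE))
  }
  fcm_finalize(x, centroids, m, metric, max_iter, FALSE)
}

# Recompute memberships and objective from the final centroids so the
# returned (centroids, memberships) pair is internally consistent (the loop's
# last u predates the last centroid update by half an iteration).
fcm_finalize <- function(x, centroids, m, metric, n_iter, converged) {
  d <- metric_distances(x, centroids, metric)
  u <- fcm_memberships(d, m)
  list(centroids = centroids, u = u, objective = sum(u^m * d^2),
       n_iter = n_iter, converged = converged)
}

#' Fit a fuzzy c-means partition
#'
#' Standard alternating FCM updates: memberships
#' `u_ij = 1 / sum_l (d_ij / d_il)^(2/(m-1))` and weighted-mean centroids
#' `c_j = sum_i u_ij^m x_i / sum_i u_ij^m`, minimising the objective
#' `J_m = sum_ij u_ij^m d_ij^2`.  Each of `n_restarts` runs starts from a
#' k-means++-style seeding; the best-objective run is returned.  Cells
#' coincident with a centroid receive full membership there.  For
#' non-Euclidean metrics the weighted-mean centroid update is retained
#' (drop-in metric substitution), which is the common generalised-FCM
#' approximation rather than the metric-specific minimiser.
#'
#' @param e An [expression_matrix()] (or numeric matrix), cells x genes.
#' @param k Number of clusters (`1 <= k <=` number of cells).  `k = 1` is
#'   the degenerate fit: the centroid is the coordinate-wise mean and all
#'   memberships are 1.
#' @param m Fuzziness coefficient (> 1); values near 1 approach hard
#'   k-means, large values push memberships toward uniform `1/k`.
#' @param metric A [distance_metric()] (default Euclidean).
#' @param n_restarts Number of seeded restarts (default 20).
#' @param seed Integer seed.
#' @param tol Convergence tolerance on the relative objective change or the
#'   maximum membership change (default 1e-6).
#' @param max_iter Iteration cap per restart (default 1000); exceeding it
#'   returns `converged = FALSE` with a warning.
#' @return A `cluster_model` with fields `centroids`, `memberships`, `m`,
#'   `k`, `metric`, `objective`, `n_iter`, `converged`, `seed`.
#' @export
fcm_fit <- function(e, k, m = 2, metric = distance_metric("euclidean"),
                    n_restarts = 20, seed = 1, tol = 1e-6, max_iter = 1000) {
  x <- as_values(e)
  n <- nrow(x)
  if (k > n) stop("k cannot exceed the number of cells")
  if (k < 1) stop("k must be >= 1")
  if (m <= 1) stop("fuzziness coefficient m must be > 1")
  if (k == 1) {
    centroid <- matrix(colMeans(x), 1, ncol(x), dimnames = list(NULL, colnames(x)))
    d <- metric_distances(x, centroid, metric)
    return(new_cluster_model(centroid, matrix(1, n, 1), m, 1L, metric,
                             sum(d^2), 0L, TRUE, seed, rownames(x)))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      run <- fcm_single_run(x, k, m, metric, tol, max_iter)
      if (is.null(best) || run$objective < best$objective) best <- run
    }
  })
  if (!best$converged)
    warning(sprintf("FCM did not converge within %d iterations", max_iter))
  colnames(best$centroids) <- colnames(x)
  new_cluster_model(best$centroids, best$u, m, as.integer(k), metric,
                    best$objective, best$n_iter, best$converged, seed,
                    rownames(x))
}

#' Fit a hard k-means partition
#'
#' Wraps [stats::kmeans()] (multiple seeded starts) and returns the result
#' as a `cluster_model` with 0/1 memberships, so downstream scoring,
#' projection and agreement functions apply uniformly.
#'
#' @param e An [expression_matrix()] or numeric matrix.
#' @param k Number of clusters.
#' @param n_restarts Number of random starts (default 20).
#' @param seed Integer seed.
#' @return A `cluster_model` with hard (0/1) memberships and `m = 1`.
#' @export
kmeans_fit <- function(e, k, n_restarts = 20, seed = 1) {
  x <- as_values(e)
  n <- nrow(x)
  if (k > n) stop("k cannot exceed the number of cells")
  if (k == n) {
    # every cell its own centroid: the exact zero-objective partition
    u <- diag(n)
    return(new_cluster_model(x, u, 1, as.integer(k),
                             distance_metric("euclidean"), 0, 0L, TRUE, seed,
                             rownames(x)))
  }
  km <- with_seed(seed, stats::kmeans(x, centers = k, nstart = n_restarts,
                                      iter.max = 100))
  u <- matrix(0, n, k)
  u[cbind(seq_len(n), km$cluster)] <- 1
  new_cluster_model(km$centers, u, 1, as.integer(k),
                    distance_metric("euclidean"), km$tot.withinss,
                    as.integer(km$iter), TRUE, seed, rownames(x))
}

#' Hard cluster assignment of a model
#'
#' Argmax membership per cell; ties broken toward the lowest cluster index
#' (noted via a message when they occur).
#'
#' @param model A `cluster_model`, or a memberships matrix.
#' @return Integer vector of cluster indices.
#' @export
hard_assignment <- function(model) {
  u <- if (inherits(model, "cluster_model")) model$memberships else model
  ties <- apply(u, 1, function(r) sum(r == max(r)) > 1)
  if (any(ties))
    message(sprintf("hard_assignment: %d membership ties broken toward the lowest cluster index",
                    sum(ties)))
  max.col(u, ties.method = "first")
}

#' Project a new cell population onto fixed cluster centroids
#'
#' Computes fuzzy memberships of new cells from the FCM membership formula
#' with the model's centroids held fixed (no refit), using the model's
#' fuzziness and metric; then tabulates occupancy as the fraction of cells
#' hard-assigned to each cluster.
#'
#' @param model A `cluster_model` fit on the reference population.
#' @param e_new An [expression_matrix()] sharing the model's gene panel and
#'   normalisation convention.
#' @return A list with `memberships` (cells x k) and `occupancy` (an
#'   `occupancy_table`: per-cluster fractions summing to 1).
#' @export
project_population <- function(model, e_new) {
  x <- as_values(e_new)
  panel <- colnames(model$centroids)
  if (!all(panel %in% colnames(x)))
    stop("new population lacks genes of the model's panel")
  x <- x[, panel, drop = FALSE]
  d <- metric_distances(x, model$centroids, model$metric)
  u <- if (model$m > 1) fcm_memberships(d, model$m) else {
    h <- matrix(0, nrow(x), model$k)
    h[cbind(seq_len(nrow(x)), max.col(-d, ties.method = "first"))] <- 1
    h
  }
  dimnames(u) <- list(rownames(x), rownames(model$centroids))
  hard <- hard_assignment(u)
  occ <- tabulate(hard, nbins = model$k) / nrow(x)
  list(memberships = u, occupancy = occupancy_table(occ))
}

#' Per-cluster occupancy table
#'
#' @param fractions Nonnegative per-cluster fractions summing to 1.
#' @param population_label Free-text label.
#' @return An object of class `occupancy_table`.
#' @export
occupancy_table <- function(fractions, population_label = "") {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("occupancy fractions must be nonnegative and sum to 1")
  structure(list(fractions = fractions, population_label = population_label),
            class = "occupancy_table")
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat("<occupancy_table>", x$population_label, "\n")
  print(round(100 * x$fractions, 1))
  invisible(x)
}

#' Agreement between two partitions (adjusted Rand index)
#'
#' Hardens both models (argmax membership) and computes the adjusted Rand
#' index, which is 1 for identical partitions (up to label permutation) and
#' has expectation 0 for independent random partitions.
#'
#' @param a,b `cluster_model` objects on the same cells, or integer label
#'   vectors.
#' @return The adjusted Rand index.
#' @export
partition_agreement <- function(a, b) {
  la <- if (inherits(a, "cluster_model")) hard_assignment(a) else as.integer(a)
  lb <- if (inherits(b, "cluster_model")) hard_assignment(b) else as.integer(b)
  if (length(la) != length(lb)) stop("partitions cover different cells")
  mclust::adjustedRandIndex(la, lb)
}
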