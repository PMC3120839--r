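# Cluster-stability diagnostics: bootstrap distribution of the optimal
# cluster number, prediction-strength validation, and gene-panel/metric
# sensitivity.

#' Bootstrap distribution of the AICc-optimal cluster number
#'
#' Repeatedly draws subsets of cells (without replacement by default, i.e.
#' distinct-cell subsets; set `replace = TRUE` for a classical bootstrap),
#' reruns the full [optimize_grid()] search on each subset, and tabulates
#' which cluster number wins.
#'
#' @param e An [expression_matrix()] or numeric matrix.
#' @param grid A [model_grid()].
#' @param fraction Subsample fraction of cells in (0, 1] (default 0.7).
#' @param n_iterations Number of subsamples (default 100).
#' @param seed Integer seed.
#' @param replace Sample cells with replacement (default `FALSE`).
#' @param n_restarts Restarts per grid point (default 3).
#' @return A list of class `bootstrap_cluster_report`: `n_iterations`,
#'   `subsample_fraction`, `k_frequencies` (named fractions summing to 1),
#'   `mean_k`, `sd_k`, `ks` (per-iteration selections).
#' @export
bootstrap_cluster_number <- function(e, grid = model_grid(), fraction = 0.7,
                                     n_iterations = 100, seed = 1,
                                     replace = FALSE, n_restarts = 3) {
  x <- as_values(e)
  n <- nrow(x)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  n_sub <- round(fraction * n)
  if (n_sub < max(grid$k_values)) stop("subsample smaller than the largest k in the grid")
  seeds <- derive_seeds(seed, 2 * n_iterations)
  ks <- integer(n_iterations)
  for (b in seq_len(n_iterations)) {
    idx <- with_seed(seeds[b], sample.int(n, n_sub, replace = replace))
    opt <- optimize_grid(x[idx, , drop = FALSE], grid,
                         n_restarts = n_restarts, seed = seeds[n_iterations + b])
    ks[b] <- opt$best$k
  }
  freq <- table(factor(ks, levels = grid$k_values)) / n_iterations
  structure(list(n_iterations = n_iterations, subsample_fraction = fraction,
                 k_frequencies = c(freq), mean_k = mean(ks),
                 sd_k = stats::sd(ks), ks = ks),
            class = "bootstrap_cluster_report")
}

#' @export
print.bootstrap_cluster_report <- function(x, ...) {
  cat(sprintf("<bootstrap_cluster_report> %d subsets of %.0f%% of cells\n",
              x$n_iterations, 100 * x$subsample_fraction))
  cat(sprintf("  mean k = %.2f, sd = %.2f\n", x$mean_k, x$sd_k))
  print(round(x$k_frequencies, 3))
  invisible(x)
}

# Prediction-strength contribution of one train/test split at one k.
ps_one_split <- function(x_train, x_test, k, n_restarts, seed_pair) {
  if (k == 1) return(1)
  km_train <- kmeans_fit(x_train, k, n_restarts = n_restarts, seed = seed_pair[1])
  km_test <- kmeans_fit(x_test, k, n_restarts = n_restarts, seed = seed_pair[2])
  test_labels <- hard_assignment(km_test)
  # classify test cells by nearest TRAIN centroid
  d <- metric_distances(x_test, km_train$centroids, distance_metric("euclidean"))
  train_labels <- max.col(-d, ties.method = "first")
  ps_clusters <- vapply(seq_len(k), function(c_id) {
    members <- which(test_labels == c_id)
    n_c <- length(members)
    if (n_c < 2) return(1)  # degenerate cluster contributes 1 by convention
    counts <- tabulate(train_labels[members], nbins = k)
    sum(counts * (counts - 1)) / (n_c * (n_c - 1))
  }, numeric(1))
  min(ps_clusters)
}

#' Prediction strength of candidate cluster numbers
#'
#' Cross-validated cluster validity in the Tibshirani-Walther sense: for
#' each fold, cluster the training and test sets separately with k-means;
#' classify test cells by their nearest training centroid; for each test
#' cluster compute the proportion of its within-cluster cell pairs that are
#' also co-assigned under the training classification; the prediction
#' strength at `k` is the minimum over test clusters, averaged over folds
#' and iterations.  `ps(1) = 1` by convention.  The chosen `k` is the
#' largest whose mean prediction strength exceeds the threshold.
#'
#' @param e An [expression_matrix()] or numeric matrix.
#' @param k_values Candidate cluster numbers (default 1..6).
#' @param n_folds Cross-validation folds (default 5).
#' @param n_iterations Repeated fold-shuffles (default 100).
#' @param threshold Validity threshold (default 0.8).
#' @param seed Integer seed.
#' @param n_restarts k-means restarts (default 5).
#' @return A list of class `prediction_strength_report`: `table`
#'   (data.frame `k`, `mean_ps`, `sd_ps`), `chosen_k`, `threshold`,
#'   `n_folds`, `n_iterations`.
#' @export
prediction_strength <- function(e, k_values = 1:6, n_folds = 5,
                                n_iterations = 100, threshold = 0.8, seed = 1,
                                n_restarts = 5) {
  x <- as_values(e)
  n <- nrow(x)
  if (n_folds < 2) stop("n_folds must be >= 2")
  seeds <- derive_seeds(seed, n_iterations)
  per_k <- matrix(NA_real_, n_iterations, length(k_values))
  for (it in seq_len(n_iterations)) {
    folds <- with_seed(seeds[it], sample(rep_len(seq_len(n_folds), n)))
    split_seeds <- derive_seeds(seeds[it] + 1L, 2 * n_folds * length(k_values))
    s <- 0L
    for (ki in seq_along(k_values)) {
      vals <- numeric(n_folds)
      for (f in seq_len(n_folds)) {
        s <- s + 2L
        test <- folds == f
        vals[f] <- ps_one_split(x[!test, , drop = FALSE], x[test, , drop = FALSE],
                                k_values[ki], n_restarts,
                                split_seeds[(s - 1L):s])
      }
      per_k[it, ki] <- mean(vals)
    }
  }
  tab <- data.frame(k = k_values, mean_ps = colMeans(per_k),
                    sd_ps = apply(per_k, 2, stats::sd))
  above <- tab$k[tab$mean_ps > threshold]
  chosen <- if (length(above)) max(above) else min(k_values)
  structure(list(table = tab, chosen_k = chosen, threshold = threshold,
                 n_folds = n_folds, n_iterations = n_iterations),
            class = "prediction_strength_report")
}

#' @export
print.prediction_strength_report <- function(x, ...) {
  cat(sprintf("<prediction_strength_report> %d-fold CV, %d iterations, threshold %.2f\n",
              x$n_folds, x$n_iterations, x$threshold))
  print(transform(x$table, mean_ps = round(mean_ps, 3), sd_ps = round(sd_ps, 3)))
  cat("chosen k =", x$chosen_k, "\n")
  invisible(x)
}

#' Sensitivity of the optimal partition to the gene panel
#'
#' Reruns [optimize_grid()] restricted to each supplied gene panel and
#' compares the resulting hard partitions to the first panel's (the
#' reference) by adjusted Rand index.
#'
#' @param e An [expression_matrix()] or numeric matrix.
#' @param panels Named list of gene-id vectors; the first is the reference.
#' @param grid A [model_grid()].
#' @param seed Integer seed.
#' @param n_restarts Restarts per grid point (default 3).
#' @return A data.frame with `panel`, `n_genes`, `best_k`, `best_m`,
#'   `ari_vs_reference`.
#' @export
gene_panel_sensitivity <- function(e, panels, grid = model_grid(), seed = 1,
                                   n_restarts = 3) {
  x <- as_values(e)
  if (!length(panels)) stop("no gene panels supplied")
  if (is.null(names(panels))) names(panels) <- paste0("panel", seq_along(panels))
  seeds <- derive_seeds(seed, length(panels))
  fits <- lapply(seq_along(panels), function(i) {
    genes <- panels[[i]]
    if (!length(genes)) stop("empty gene panel: ", names(panels)[i])
    if (!all(genes %in% colnames(x))) stop("panel genes missing from the matrix")
    optimize_grid(x[, genes, drop = FALSE], grid,
                  n_restarts = n_restarts, seed = seeds[i])
  })
  ref_labels <- hard_assignment(fits[[1]]$best)
  do.call(rbind, lapply(seq_along(panels), function(i) {
    data.frame(panel = names(panels)[i], n_genes = length(panels[[i]]),
               best_k = fits[[i]]$best$k, best_m = fits[[i]]$best$m,
               ari_vs_reference = partition_agreement(ref_labels,
                                                      hard_assignment(fits[[i]]$best)),
               stringsAsFactors = FALSE)
  }))
}
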