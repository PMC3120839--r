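# Information-theoretic selection of cluster number and fuzziness by
# exhaustive AICc grid search, with Akaike weights and evidence ratios.

#' Grid of candidate clustering parameters
#'
#' @param k_values Candidate cluster numbers (default 1..6).
#' @param m_values Candidate fuzziness coefficients (> 1; default 1.05 to
#'   3.00 in steps of 0.05, so the low-fuzziness region near hard
#'   clustering is representable).
#' @return An object of class `model_grid`.
#' @export
model_grid <- function(k_values = 1:6, m_values = seq(1.05, 3, by = 0.05)) {
  if (!length(k_values) || !length(m_values)) stop("grid must be non-empty")
  if (any(k_values < 1)) stop("k must be >= 1")
  if (any(m_values <= 1)) stop("fuzziness values must be > 1")
  structure(list(k_values = sort(unique(as.integer(k_values))),
                 m_values = sort(unique(m_values))),
            class = "model_grid")
}

#' Score a fitted cluster model by a Gaussian-mixture pseudo-likelihood
#'
#' Attaches a likelihood to a fuzzy partition by reading the FCM
#' memberships as mixture responsibilities: mixing weights `pi_j` are the
#' mean memberships, a single pooled spherical variance is estimated as
#' `sigma2 = sum_ij u_ij d_ij^2 / (n g)` (Euclidean distances), and
#' `logL = sum_i log sum_j pi_j phi(x_i; c_j, sigma2 I)`.  The parameter
#' count is `K = k g + (k - 1) + 1` (centroids, mixing weights, variance);
#' the fuzziness coefficient is treated as a selected hyperparameter, not a
#' counted parameter.  Then `AIC = -2 logL + 2K` and
#' `AICc = AIC + 2K(K + 1)/(n - K - 1)`, the second-order small-sample
#' correction.  At `k = 1` this reduces to the spherical Gaussian fit at
#' the mean with its maximum-likelihood variance.
#'
#' @param model A `cluster_model` fit on `e`.
#' @param e The [expression_matrix()] (or matrix) the model was fit on.
#' @return A one-row data.frame: `k`, `m`, `log_likelihood`, `n_params`,
#'   `aic`, `aicc` (`NA` with a warning when `n <= K + 1`).
#' @export
score_model <- function(model, e) {
  x <- as_values(e)
  panel <- colnames(model$centroids)
  x <- x[, panel, drop = FALSE]
  n <- nrow(x); g <- ncol(x); k <- model$k
  d <- metric_distances(x, model$centroids, distance_metric("euclidean"))
  u <- model$memberships
  sigma2 <- sum(u * d^2) / (n * g)
  sigma2 <- max(sigma2, .Machine$double.eps)
  pi_j <- colMeans(u)
  # log-sum-exp over component log densities
  logdens <- -0.5 * (g * log(2 * pi * sigma2) + d^2 / sigma2)
  logdens <- sweep(logdens, 2, log(pmax(pi_j, .Machine$double.xmin)), "+")
  mx <- apply(logdens, 1, max)
  logL <- sum(mx + log(rowSums(exp(logdens - mx))))
  K <- k * g + (k - 1) + 1
  aic <- -2 * logL + 2 * K
  if (n <= K + 1) {
    warning(sprintf("AICc undefined for k = %d (n = %d <= K + 1 = %d)", k, n, K + 1))
    aicc <- NA_real_
  } else {
    aicc <- aic + 2 * K * (K + 1) / (n - K - 1)
  }
  data.frame(k = k, m = model$m, log_likelihood = logL, n_params = K,
             aic = aic, aicc = aicc)
}

#' Exhaustive AICc optimisation over a (k, m) grid
#'
#' Fits [fcm_fit()] at every grid point (the `k = 1` point is the
#' degenerate single-centroid fit, scored once), scores each fit with
#' [score_model()], and returns the AICc-minimising model together with the
#' full score table carrying AICc differences `delta = AICc_i - min AICc`,
#' Akaike weights `w_i = exp(-delta_i/2) / sum_l exp(-delta_l/2)` and
#' evidence ratios `w_best / w_i`.  Ties on AICc are broken toward smaller
#' `k`, then smaller `m` (parsimony first).
#'
#' @param e An [expression_matrix()] or numeric matrix.
#' @param grid A [model_grid()].
#' @param metric A [distance_metric()] passed to the fits.
#' @param n_restarts Restarts per grid point (default 5).
#' @param seed Integer seed; per-grid-point seeds are derived from it.
#' @param tol,max_iter Passed to [fcm_fit()].
#' @return A list with `best` (the winning `cluster_model`) and `scores`
#'   (data.frame with `k`, `m`, `log_likelihood`, `n_params`, `aic`,
#'   `aicc`, `delta_aic`, `akaike_weight`, `evidence_ratio`).
#' @export
optimize_grid <- function(e, grid = model_grid(), metric = distance_metric("euclidean"),
                          n_restarts = 5, seed = 1, tol = 1e-6, max_iter = 1000) {
  stopifnot(inherits(grid, "model_grid"))
  x <- as_values(e)
  pts <- expand.grid(m = grid$m_values, k = grid$k_values)[, c("k", "m")]
  # k = 1 does not depend on m: score the first m only
  keep <- !(pts$k == 1 & duplicated(pts$k))
  pts <- pts[keep, , drop = FALSE]
  seeds <- derive_seeds(seed, nrow(pts))
  scores <- vector("list", nrow(pts))
  models <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    fit <- fcm_fit(x, k = pts$k[i], m = pts$m[i], metric = metric,
                   n_restarts = n_restarts, seed = seeds[i],
                   tol = tol, max_iter = max_iter)
    models[[i]] <- fit
    scores[[i]] <- score_model(fit, x)
  }
  tab <- do.call(rbind, scores)
  ok <- !is.na(tab$aicc)
  if (!any(ok)) stop("AICc undefined at every grid point")
  tab <- tab[ok, , drop = FALSE]
  models <- models[ok]
  # parsimony-first tie-break: order by (aicc, k, m), best is row 1
  ord <- order(tab$aicc, tab$k, tab$m)
  tab <- tab[ord, , drop = FALSE]
  models <- models[ord]
  tab$delta_aic <- tab$aicc - tab$aicc[1]
  w <- exp(-tab$delta_aic / 2)
  tab$akaike_weight <- w / sum(w)
  tab$evidence_ratio <- tab$akaike_weight[1] / tab$akaike_weight
  rownames(tab) <- NULL
  list(best = models[[1]], scores = tab)
}

#' Model-selection uncertainty report
#'
#' @param scores The score table from [optimize_grid()].
#' @param top Number of rows to keep (default all).
#' @return The table sorted by AICc difference ascending, columns `k`, `m`,
#'   `aicc`, `delta_aic`, `akaike_weight`, `evidence_ratio`.
#' @export
model_selection_report <- function(scores, top = nrow(scores)) {
  if (!nrow(scores)) stop("no scores to report")
  ord <- order(scores$delta_aic, scores$k, scores$m)
  out <- scores[ord, c("k", "m", "aicc", "delta_aic", "akaike_weight", "evidence_ratio")]
  rownames(out) <- NULL
  utils::head(out, top)
}
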