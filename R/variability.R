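# Coefficient-of-variation statistics with bootstrap uncertainty.

new_cov_estimate <- function(gene_id, cov, boot_sd = NA_real_, n_boot = 0L) {
  structure(list(gene_id = gene_id, cov = cov, boot_sd = boot_sd,
                 n_boot = as.integer(n_boot)),
            class = "cov_estimate")
}

#' @export
print.cov_estimate <- function(x, ...) {
  cat(sprintf("<cov_estimate> %s: cov = %.4g", x$gene_id, x$cov))
  if (x$n_boot > 0) cat(sprintf(" (boot sd %.4g over %d resamples)", x$boot_sd, x$n_boot))
  cat("\n")
  invisible(x)
}

#' Univariate coefficient of variation of one gene
#'
#' `cov = sd / mean` with the sample (n-1) standard deviation, a
#' scale-invariant summary of single-gene variability.  Computed on the
#' scale of the values supplied; for qPCR panels the conventional scale is
#' raw Ct cycles (see [select_top_cov_genes()]).
#'
#' @param values Numeric vector of per-cell values for one gene (>= 2
#'   values, nonzero mean).
#' @param gene_id Identifier attached to the result.
#' @return A `cov_estimate` with elements `gene_id`, `cov`, `boot_sd`,
#'   `n_boot`.
#' @examples
#' gene_cov(c(1, 2, 3))$cov   # sd 1, mean 2 -> 0.5
#' @export
gene_cov <- function(values, gene_id = "gene") {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need >= 2 values")
  mu <- mean(values)
  if (mu == 0) stop("COV undefined: mean is 0 (consider shifting the scale)")
  new_cov_estimate(gene_id, stats::sd(values) / mu)
}

#' Multivariate coefficient of variation over a gene set
#'
#' The pooled generalisation `cv_n = sqrt(sum_i sigma_i^2) / sqrt(sum_i
#' mu_i^2)` (Van Valen 1974), a standardized scale-invariant index of
#' dispersion over a set of genes.  For a single gene it reduces to
#' [gene_cov()].
#'
#' @param x A [ct_matrix()], [expression_matrix()] or numeric matrix
#'   (cells x genes).
#' @param genes Optional gene subset (names or indices); default all.
#' @return A `cov_estimate` with `gene_id = "multivariate"`.
#' @export
multivariate_cov <- function(x, genes = NULL) {
  v <- as_values(x)
  if (!is.null(genes)) v <- v[, genes, drop = FALSE]
  if (nrow(v) < 2) stop("need >= 2 cells")
  mus <- colMeans(v)
  sig2 <- apply(v, 2, stats::var)
  denom <- sqrt(sum(mus^2))
  if (denom == 0) stop("COV undefined: all gene means are 0")
  new_cov_estimate("multivariate", sqrt(sum(sig2)) / denom)
}

#' Bootstrap standard deviation of a gene's coefficient of variation
#'
#' Resamples cells with replacement `n_boot` times, recomputes [gene_cov()]
#' on each resample, and reports the standard deviation of the resampled
#' COVs.  Resamples with zero mean (for which the COV is undefined) are
#' redrawn and counted in a message.
#'
#' @param values Numeric vector of per-cell values for one gene.
#' @param n_boot Number of bootstrap resamples (default 1e5).
#' @param seed Integer seed.
#' @param gene_id Identifier attached to the result.
#' @return A `cov_estimate` with `cov` from the full sample and `boot_sd`
#'   from the resamples.
#' @export
bootstrap_cov_sd <- function(values, n_boot = 1e5, seed = 1, gene_id = "gene") {
  values <- as.numeric(values)
  est <- gene_cov(values, gene_id)
  n <- length(values)
  covs <- with_seed(seed, {
    out <- numeric(n_boot)
    redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        res <- values[sample.int(n, n, replace = TRUE)]
        mu <- mean(res)
        if (mu != 0) break
        redrawn <- redrawn + 1L
      }
      out[b] <- stats::sd(res) / mu
    }
    if (redrawn > 0)
      message(sprintf("bootstrap_cov_sd: redrew %d zero-mean resamples", redrawn))
    out
  })
  est$boot_sd <- stats::sd(covs)
  est$n_boot <- as.integer(n_boot)
  est
}

#' Per-gene COV table for a Ct matrix
#'
#' Convenience wrapper computing [gene_cov()] (and optionally
#' [bootstrap_cov_sd()]) for every gene of a matrix.
#'
#' @param x A [ct_matrix()], [expression_matrix()] or numeric matrix.
#' @param n_boot Bootstrap resamples per gene; 0 (default) skips the
#'   bootstrap.
#' @param seed Integer seed for the bootstrap.
#' @return A data.frame with columns `gene`, `cov`, `boot_sd`, `n`.
#' @export
cov_table <- function(x, n_boot = 0, seed = 1) {
  v <- as_values(x)
  genes <- colnames(v)
  seeds <- if (n_boot > 0) derive_seeds(seed, ncol(v)) else integer(ncol(v))
  rows <- lapply(seq_len(ncol(v)), function(j) {
    est <- if (n_boot > 0)
      bootstrap_cov_sd(v[, j], n_boot = n_boot, seed = seeds[j], gene_id = genes[j])
    else gene_cov(v[, j], gene_id = genes[j])
    data.frame(gene = genes[j], cov = est$cov, boot_sd = est$boot_sd,
               n = nrow(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
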