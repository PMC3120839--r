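# Differential-distribution gene selection between two cell populations.

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Computes the KS statistic `D = sup_x |ECDF_a(x) - ECDF_b(x)|` and its
#' two-sided asymptotic p-value.  Asymptotic (rather than exact) p-values
#' are used throughout because Ct data carry heavy ties at the detection
#' floor, which invalidate the exact no-ties formulas; a message notes when
#' the tie fraction exceeds 5%.
#'
#' @param a,b Numeric vectors of per-cell values (each >= 2 values).
#' @param gene_id Identifier attached to the result.
#' @return A list of class `gene_test` with `gene_id`, `ks_statistic`,
#'   `p_value` (and `p_adjusted`, `selected` set to `NA` until adjusted).
#' @export
ks_compare <- function(a, b, gene_id = "gene") {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs >= 2 values")
  tie_frac <- 1 - length(unique(c(a, b))) / (length(a) + length(b))
  if (tie_frac > 0.05)
    message(sprintf("ks_compare[%s]: tie fraction %.1f%%; asymptotic p-values used",
                    gene_id, 100 * tie_frac))
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  structure(list(gene_id = gene_id,
                 ks_statistic = unname(kt$statistic),
                 p_value = kt$p.value,
                 p_adjusted = NA_real_, selected = NA),
            class = "gene_test")
}

#' Select genes with differential expression distributions
#'
#' Runs a per-gene two-sample KS test between two populations over their
#' shared gene panel, applies a Bonferroni correction (`p_adjusted =
#' min(1, p * n_tests)`), and flags genes with `p_adjusted < alpha`.
#'
#' @param pop_a,pop_b Two [expression_matrix()] (or [ct_matrix()]) objects
#'   sharing gene ids; by convention the normalised (clamped) matrices.
#' @param alpha Family-wise significance level (default 0.01).
#' @param n_tests Bonferroni multiplier; defaults to the number of shared
#'   genes tested.
#' @param method Multiple-testing correction: `"bonferroni"` (the default
#'   and the method this package's selection contract is stated for) or
#'   `"BH"` for a Benjamini-Hochberg false-discovery-rate alternative.
#' @return A data.frame with one row per shared gene: `gene`, `ks_statistic`,
#'   `p_value`, `p_adjusted`, `selected`.
#' @export
select_differential_genes <- function(pop_a, pop_b, alpha = 0.01, n_tests = NULL,
                                      method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  va <- as_values(pop_a); vb <- as_values(pop_b)
  shared <- intersect(colnames(va), colnames(vb))
  if (length(shared) == 0) stop("populations share no genes")
  if (is.null(n_tests)) n_tests <- length(shared)
  rows <- lapply(shared, function(g) {
    kt <- ks_compare(va[, g], vb[, g], gene_id = g)
    data.frame(gene = g, ks_statistic = kt$ks_statistic, p_value = kt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (method == "bonferroni") pmin(1, out$p_value * n_tests)
                    else stats::p.adjust(out$p_value, method = "BH")
  out$selected <- out$p_adjusted < alpha
  out
}

#' Select the genes with the highest coefficients of variation
#'
#' Alternate feature selection: ranks genes by [gene_cov()] (descending),
#' breaking ties lexicographically by gene id, and returns the top
#' `n_genes`.  COV is conventionally computed on the raw Ct scale, where
#' means are positive; for a median-centred [expression_matrix()] the
#' values are first mapped to the linear scale `2^e`.
#'
#' @param x A [ct_matrix()], [expression_matrix()] or numeric matrix.
#' @param n_genes Number of genes to return (<= panel size).
#' @return Character vector of gene ids, highest COV first.
#' @export
select_top_cov_genes <- function(x, n_genes) {
  v <- as_values(x)
  if (inherits(x, "expression_matrix")) v <- 2^v
  if (n_genes > ncol(v)) stop("n_genes exceeds the gene panel size")
  covs <- vapply(seq_len(ncol(v)), function(j) gene_cov(v[, j])$cov, numeric(1))
  ord <- order(-covs, colnames(v))
  colnames(v)[ord][seq_len(n_genes)]
}
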