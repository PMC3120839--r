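# End-to-end orchestration: normalize -> select genes -> optimise clustering
# -> project populations -> stability reports -> ordered heatmap export.

#' Hierarchical display ordering of cells
#'
#' Agglomerative clustering (average linkage, Euclidean distance) of cells,
#' returning the dendrogram leaf order.  Used to sub-order cells within
#' each fuzzy cluster for heatmap display; apply to the transposed matrix
#' to order genes the same way.
#'
#' @param e An [expression_matrix()] or numeric matrix.
#' @param cells Optional subset of cell ids (or indices) to order.
#' @return Character vector of cell ids in leaf order.
#' @export
hierarchical_order <- function(e, cells = NULL) {
  x <- as_values(e)
  if (!is.null(cells)) x <- x[cells, , drop = FALSE]
  if (nrow(x) == 1) return(rownames(x))
  hc <- stats::hclust(stats::dist(x), method = "average")
  rownames(x)[hc$order]
}

#' Export a reordered heatmap matrix
#'
#' Writes the expression matrix with rows and columns permuted into the
#' supplied display orders, as a delimited table of log2 fold-change values
#' (bounded by the clamp, e.g. 32-fold at the default +/- 5), ready for
#' external plotting.
#'
#' @param e An [expression_matrix()].
#' @param cell_order Permutation of the cell ids.
#' @param gene_order Permutation of the gene ids.
#' @param path Output path (`.csv` comma, otherwise tab).
#' @return Invisibly, the path.
#' @export
export_heatmap_matrix <- function(e, cell_order = e$cell_ids,
                                  gene_order = e$gene_ids, path) {
  stopifnot(inherits(e, "expression_matrix"))
  if (!setequal(cell_order, e$cell_ids) || anyDuplicated(cell_order))
    stop("cell_order must be a permutation of the cell ids")
  if (!setequal(gene_order, e$gene_ids) || anyDuplicated(gene_order))
    stop("gene_order must be a permutation of the gene ids")
  write_numeric_table(e$values[cell_order, gene_order, drop = FALSE], path)
  invisible(path)
}

#' Order cells by cluster, hierarchically within each cluster
#'
#' @param e An [expression_matrix()].
#' @param model A `cluster_model` on the same cells.
#' @return Character vector of cell ids: clusters in index order, cells
#'   within each cluster in [hierarchical_order()].
#' @export
cluster_display_order <- function(e, model) {
  labels <- hard_assignment(model)
  unlist(lapply(seq_len(model$k), function(c_id) {
    members <- e$cell_ids[labels == c_id]
    if (length(members) <= 1) members else hierarchical_order(e, members)
  }), use.names = FALSE)
}

#' Assemble a pipeline run configuration
#'
#' @param inputs Named list/vector of Ct table paths (or `ct_matrix`
#'   objects), one per population.
#' @param reference Name of the reference population (centroids are fit on
#'   it).
#' @param comparison Name of the population KS-compared against the
#'   reference for gene selection (default: the first non-reference input).
#' @param lod_ct Detection floor (default 40).
#' @param clamp_bound Normalisation clamp in cycles (default 5).
#' @param pooled_median Normalise against pooled per-gene medians across
#'   all populations (default `TRUE`) rather than per-population medians.
#' @param alpha Family-wise KS significance level (default 0.01).
#' @param grid A [model_grid()].
#' @param n_restarts Restarts per grid point (default 5).
#' @param seed Master seed; stage seeds are derived from it.
#' @param output_dir Directory for artifacts.
#' @param blind Strip population labels before clustering (default `TRUE`);
#'   labels are restored for reporting.
#' @param run_stability Also run the bootstrap / prediction-strength /
#'   panel-sensitivity suite (default `FALSE`; these dominate runtime).
#' @param stability_iterations Iterations for the stability suite
#'   (default 50 bootstrap, 20 prediction-strength fold shuffles).
#' @return A list of class `run_config`.
#' @export
run_config <- function(inputs, reference, comparison = NULL, lod_ct = 40,
                       clamp_bound = 5, pooled_median = TRUE, alpha = 0.01,
                       grid = model_grid(), n_restarts = 5, seed = 1,
                       output_dir = tempfile("ctrun"), blind = TRUE,
                       run_stability = FALSE,
                       stability_iterations = c(bootstrap = 50, ps = 20)) {
  if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
    stop("inputs must be named by population")
  if (!reference %in% names(inputs))
    stop("reference population '", reference, "' is not among the inputs")
  if (is.null(comparison)) {
    others <- setdiff(names(inputs), reference)
    if (!length(others)) stop("need at least one non-reference population for gene selection")
    comparison <- others[1]
  }
  if (!comparison %in% names(inputs)) stop("comparison population not among the inputs")
  structure(list(inputs = inputs, reference = reference, comparison = comparison,
                 lod_ct = lod_ct, clamp_bound = clamp_bound,
                 pooled_median = pooled_median, alpha = alpha, grid = grid,
                 n_restarts = n_restarts, seed = seed, output_dir = output_dir,
                 blind = blind, run_stability = run_stability,
                 stability_iterations = stability_iterations),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Accepts the same keys as [run_config()]; `grid` may be given as
#' `k_values` / `m_values` lists.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  grid <- if (!is.null(y$grid))
    model_grid(k_values = unlist(y$grid$k_values),
               m_values = unlist(y$grid$m_values))
  else model_grid()
  run_config(inputs = unlist(y$inputs), reference = y$reference,
             comparison = y$comparison,
             lod_ct = y$lod_ct %||% 40, clamp_bound = y$clamp_bound %||% 5,
             pooled_median = y$pooled_median %||% TRUE,
             alpha = y$alpha %||% 0.01, grid = grid,
             n_restarts = y$n_restarts %||% 5, seed = y$seed %||% 1,
             output_dir = y$output_dir %||% tempfile("ctrun"),
             blind = y$blind %||% TRUE,
             run_stability = y$run_stability %||% FALSE)
}

write_df <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: read and pool the populations; gene-wise
#' median-centred normalisation (pooled medians by default); KS selection
#' of differential genes (reference vs comparison population); AICc grid
#' optimisation of the fuzzy partition on the reference restricted to the
#' selected genes; projection of every other population onto the fixed
#' centroids; occupancy tables; optional stability suite; hierarchical
#' within-cluster ordering and heatmap matrix export; and a JSON manifest
#' listing every artifact with the seeds and parameters that produced it.
#'
#' @param cfg A [run_config()] or path to a YAML config.
#' @return A list of class `run_result`: `manifest` (named artifact paths),
#'   `selected_genes`, `scores`, `best` (the reference `cluster_model`),
#'   `occupancy` (per population), and `stability` when requested.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(cfg$seed, 8)
  manifest <- list()
  art <- function(name, file) {
    manifest[[name]] <<- file.path(cfg$output_dir, file)
    manifest[[name]]
  }

  # --- read + pool ---
  cts <- lapply(names(cfg$inputs), function(nm) {
    inp <- if (is.list(cfg$inputs)) cfg$inputs[[nm]] else cfg$inputs[[nm]]
    ct <- if (inherits(inp, "ct_matrix")) inp
          else read_ct_table(inp, lod_ct = cfg$lod_ct, population_label = nm)
    if (cfg$blind) ct$population_label <- "blinded"
    ct
  })
  names(cts) <- names(cfg$inputs)

  # --- normalise (pooled medians by default) ---
  medians <- if (cfg$pooled_median) pooled_gene_medians(cts) else NULL
  exprs <- lapply(cts, function(ct)
    normalize_ct(ct, clamp_bound = cfg$clamp_bound,
                 gene_medians = if (cfg$pooled_median) medians else NULL))
  for (nm in names(exprs))
    write_expression_table(exprs[[nm]], art(paste0("expression_", nm),
                                            paste0("expression_", nm, ".tsv")))

  # --- KS gene selection ---
  ks_tab <- select_differential_genes(exprs[[cfg$reference]],
                                      exprs[[cfg$comparison]],
                                      alpha = cfg$alpha)
  write_df(ks_tab, art("ks_table", "ks_selection.tsv"))
  selected <- ks_tab$gene[ks_tab$selected]
  if (!length(selected))
    stop("pipeline stage 'feature_selection': no differential genes at alpha = ",
         cfg$alpha)

  # --- AICc grid optimisation on the reference, selected genes ---
  e_ref <- exprs[[cfg$reference]][, selected]
  opt <- optimize_grid(e_ref, cfg$grid, n_restarts = cfg$n_restarts,
                       seed = seeds[1])
  write_df(opt$scores, art("scores", "model_scores.tsv"))

  # --- projection + occupancy ---
  occupancy <- list()
  for (nm in names(exprs)) {
    proj <- project_population(opt$best, exprs[[nm]][, selected])
    proj$occupancy$population_label <- nm
    occupancy[[nm]] <- proj$occupancy
    occ_df <- data.frame(cluster = seq_along(proj$occupancy$fractions),
                         fraction = proj$occupancy$fractions)
    write_df(occ_df, art(paste0("occupancy_", nm), paste0("occupancy_", nm, ".tsv")))
  }

  # --- stability suite (optional) ---
  stability <- NULL
  if (isTRUE(cfg$run_stability)) {
    boot <- bootstrap_cluster_number(e_ref, cfg$grid,
                                     n_iterations = cfg$stability_iterations[["bootstrap"]],
                                     seed = seeds[2])
    ps <- prediction_strength(e_ref, k_values = cfg$grid$k_values,
                              n_iterations = cfg$stability_iterations[["ps"]],
                              seed = seeds[3])
    write_df(data.frame(k = as.integer(names(boot$k_frequencies)),
                        frequency = as.numeric(boot$k_frequencies)),
             art("bootstrap_k", "bootstrap_k.tsv"))
    write_df(ps$table, art("prediction_strength", "prediction_strength.tsv"))
    stability <- list(bootstrap = boot, prediction_strength = ps)
  }

  # --- ordered heatmap export for the reference ---
  cell_order <- cluster_display_order(e_ref, opt$best)
  gene_order <- hierarchical_order(t(e_ref$values))
  export_heatmap_matrix(e_ref, cell_order, gene_order,
                        art("heatmap_reference", "heatmap_reference.tsv"))

  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(list(seed = cfg$seed, stage_seeds = seeds,
                            reference = cfg$reference, comparison = cfg$comparison,
                            alpha = cfg$alpha, clamp_bound = cfg$clamp_bound,
                            lod_ct = cfg$lod_ct,
                            selected_genes = selected,
                            best_k = opt$best$k, best_m = opt$best$m,
                            artifacts = manifest),
                       manifest_path, auto_unbox = TRUE, digits = NA)
  structure(list(manifest = c(manifest, manifest = manifest_path),
                 selected_genes = selected, scores = opt$scores,
                 best = opt$best, occupancy = occupancy,
                 stability = stability),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result>\n")
  cat("  selected genes:", paste(x$selected_genes, collapse = ", "), "\n")
  cat(sprintf("  best model: k = %d, m = %g\n", x$best$k, x$best$m))
  for (nm in names(x$occupancy))
    cat(sprintf("  occupancy %s: %s\n", nm,
                paste(sprintf("%.1f%%", 100 * x$occupancy[[nm]]$fractions),
                      collapse = " / ")))
  invisible(x)
}
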