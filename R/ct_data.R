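# Data model and normalisation for single-cell qPCR cycle-threshold matrices.

#' Construct a cycle-threshold (Ct) matrix
#'
#' The universal input object of the package: a cells x genes matrix of qPCR
#' cycle-threshold values for one cell population.  A reaction that fails to
#' amplify within `lod_ct` cycles (a "nondetect") is stored exactly at the
#' detection floor `lod_ct`.
#'
#' @param values Numeric matrix, cells in rows, genes in columns.  All finite
#'   values must lie in `(0, lod_ct]`.
#' @param cell_ids Character vector of unique cell identifiers (defaults to
#'   `rownames(values)`).
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   `colnames(values)`).
#' @param population_label Free-text label for the cell population.
#' @param lod_ct Detection floor in qPCR cycles; nondetects are encoded as
#'   this value (default 40).
#' @return An object of class `ct_matrix` with elements `values`, `cell_ids`,
#'   `gene_ids`, `population_label`, `lod_ct`.
#' @examples
#' m <- matrix(c(12.1, 40, 18.5, 39.2), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("c1", "c2"), c("Tal1", "Mycn")))
#' ct <- ct_matrix(m, population_label = "demo")
#' n_nondetect(ct)
#' @export
ct_matrix <- function(values, cell_ids = rownames(values),
                      gene_ids = colnames(values),
                      population_label = "", lod_ct = 40) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("Ct values must be numeric")
  if (is.null(cell_ids))
    cell_ids <- as.character(sapply(seq_len(nrow(values)), function(i) paste0("cell", i)))
  if (is.null(gene_ids))
    gene_ids <- as.character(sapply(seq_len(ncol(values)), function(i) paste0("gene", i)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(cell_ids) || ncol(values) != length(gene_ids))
    stop("matrix dimensions do not match id list lengths")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids: ",
                                    paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids: ",
                                    paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  fin <- values[is.finite(values)]
  if (any(fin <= 0) || any(fin > lod_ct))
    stop("all finite Ct values must lie in (0, lod_ct]")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 population_label = population_label, lod_ct = lod_ct),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("<ct_matrix> %d cells x %d genes", length(x$cell_ids), length(x$gene_ids)))
  if (nzchar(x$population_label)) cat(sprintf(" [%s]", x$population_label))
  cat(sprintf("; lod_ct = %g; %d nondetects\n", x$lod_ct, n_nondetect(x)))
  invisible(x)
}

#' Count nondetect reactions in a Ct matrix
#' @param ct A [ct_matrix()].
#' @return Integer count of entries at the detection floor.
#' @export
n_nondetect <- function(ct) sum(ct$values == ct$lod_ct)

#' Subset a Ct matrix by cells and/or genes
#' @param x A [ct_matrix()].
#' @param i Cell index or id vector.
#' @param j Gene index or id vector.
#' @param ... Ignored.
#' @return A `ct_matrix` restricted to the requested cells/genes.
#' @export
`[.ct_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$cell_ids)
  if (missing(j)) j <- seq_along(x$gene_ids)
  v <- x$values[i, j, drop = FALSE]
  ct_matrix(v, population_label = x$population_label, lod_ct = x$lod_ct)
}

#' Construct a normalised expression matrix
#'
#' Holds gene-wise median-centred log2 expression values (fold change from
#' the pooled median), clamped to `[-clamp_bound, +clamp_bound]`.  Because one
#' qPCR cycle corresponds to a two-fold change in template, the value is in
#' log2 fold-change units; a clamp of 5 cycles bounds values at 32-fold above
#' or below the median.
#'
#' @param values Numeric matrix, cells x genes, in `[-clamp_bound, clamp_bound]`.
#' @param cell_ids,gene_ids Unique identifiers (default taken from dimnames).
#' @param clamp_bound Absolute bound in cycle thresholds (default 5).
#' @return An object of class `expression_matrix`.
#' @seealso [normalize_ct()] which builds one from a [ct_matrix()].
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values), clamp_bound = 5) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(cell_ids))
    cell_ids <- as.character(sapply(seq_len(nrow(values)), function(i) paste0("cell", i)))
  if (is.null(gene_ids))
    gene_ids <- as.character(sapply(seq_len(ncol(values)), function(i) paste0("gene", i)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(cell_ids) || ncol(values) != length(gene_ids))
    stop("matrix dimensions do not match id list lengths")
  if (anyDuplicated(cell_ids) || anyDuplicated(gene_ids))
    stop("cell and gene ids must be unique")
  if (length(values) && max(abs(values)) > clamp_bound + 1e-12)
    stop("expression values must lie within +/- clamp_bound")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 clamp_bound = clamp_bound),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d cells x %d genes; clamp = +/-%g log2 units\n",
              length(x$cell_ids), length(x$gene_ids), x$clamp_bound))
  invisible(x)
}

#' @rdname sub-.ct_matrix
#' @export
`[.expression_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$cell_ids)
  if (missing(j)) j <- seq_along(x$gene_ids)
  v <- x$values[i, j, drop = FALSE]
  expression_matrix(v, clamp_bound = x$clamp_bound)
}

#' Microfluidic chip layout
#'
#' Describes the assay x sample grid of an integrated fluidic circuit such as
#' a 48.48 dynamic array, where every assay (gene target) is run against every
#' sample (cell) in parallel.
#'
#' @param n_assays Number of assay (gene) inlets, default 48.
#' @param n_samples Number of sample (cell) inlets, default 48.
#' @return An object of class `chip_layout`.
#' @export
chip_layout <- function(n_assays = 48, n_samples = 48) {
  if (n_assays < 1 || n_samples < 1) stop("chip layout dimensions must be >= 1")
  structure(list(n_assays = as.integer(n_assays), n_samples = as.integer(n_samples)),
            class = "chip_layout")
}

#' Number of qPCR reactions per chip run
#'
#' Each chip run performs one reaction per assay x sample pair; the default
#' 48 x 48 layout therefore yields 2,304 data points.
#'
#' @param layout A [chip_layout()].
#' @return Integer reaction count.
#' @examples
#' chip_reaction_count(chip_layout())      # 2304
#' chip_reaction_count(chip_layout(48, 96))
#' @export
chip_reaction_count <- function(layout = chip_layout()) {
  stopifnot(inherits(layout, "chip_layout"))
  layout$n_assays * layout$n_samples
}

delim_for_path <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a Ct table from a delimited file
#'
#' Expects cells as rows and genes as columns, with one header row of gene
#' ids and a leading column of cell ids.  Comma- vs tab-delimited is
#' auto-detected from the file extension (`.csv` is comma, anything else
#' tab).  Values above `lod_ct` and missing values are floored/encoded to
#' `lod_ct`; the number of floored entries is reported via a message.
#'
#' @param path Path to the delimited table.
#' @param lod_ct Detection floor in cycles (default 40).
#' @param population_label Optional population label (defaults to file name).
#' @return A [ct_matrix()].
#' @export
read_ct_table <- function(path, lod_ct = 40, population_label = NULL) {
  delim <- delim_for_path(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim, row.names = 1,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "")
  vals <- suppressWarnings(vapply(seq_len(ncol(raw)), function(j)
    as.numeric(raw[[j]]), numeric(nrow(raw))))
  if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- which(is.na(vals) & !(is.na(raw) | raw == "" | toupper(as.matrix(raw)) %in% c("NA", "NAN")),
               arr.ind = TRUE)
  if (length(bad)) {
    stop(sprintf("non-numeric entry '%s' at row '%s', column '%s'",
                 as.matrix(raw)[bad[1, 1], bad[1, 2]],
                 rownames(raw)[bad[1, 1]], colnames(raw)[bad[1, 2]]))
  }
  n_floor <- sum(is.na(vals) | vals > lod_ct)
  vals[is.na(vals) | vals > lod_ct] <- lod_ct
  if (n_floor > 0)
    message(sprintf("read_ct_table: floored %d entries to lod_ct = %g", n_floor, lod_ct))
  if (is.null(population_label))
    population_label <- sub("\\.[^.]*$", "", basename(path))
  ct_matrix(vals, cell_ids = rownames(raw), gene_ids = colnames(raw),
            population_label = population_label, lod_ct = lod_ct)
}

#' Read a wide 48.48 dynamic-array "heatmap" CSV export
#'
#' Instrument software for 48.48 arrays exports an assay x sample grid (genes
#' in rows, cells in columns).  This shim transposes that layout into the
#' package's cells x genes [ct_matrix()] convention.
#'
#' @inheritParams read_ct_table
#' @return A [ct_matrix()].
#' @export
read_chip_heatmap <- function(path, lod_ct = 40, population_label = NULL) {
  ct <- read_ct_table(path, lod_ct = lod_ct, population_label = population_label)
  ct_matrix(t(ct$values), population_label = ct$population_label, lod_ct = lod_ct)
}

#' Pooled per-gene median Ct across populations
#'
#' When several populations are analysed jointly the normalisation median for
#' each gene is taken over the pooled sample of all cells.
#'
#' @param cts A list of [ct_matrix()] objects sharing a gene panel.
#' @return Named numeric vector of per-gene medians (cycles).
#' @export
pooled_gene_medians <- function(cts) {
  if (inherits(cts, "ct_matrix")) cts <- list(cts)
  genes <- cts[[1]]$gene_ids
  for (ct in cts)
    if (!identical(ct$gene_ids, genes)) stop("populations must share a gene panel")
  pooled <- do.call(rbind, lapply(cts, function(ct) ct$values))
  apply(pooled, 2, stats::median)
}

#' Normalise a Ct matrix to median-centred log2 expression
#'
#' For cell i and gene g the normalised value is
#' `e_ig = clamp(median_g - Ct_ig, -clamp_bound, +clamp_bound)`, where
#' `median_g` is the per-gene median Ct over the pooled sample.  The sign
#' convention makes higher values mean more mRNA (fewer cycles to
#' detection).  Nondetects sit at the detection floor and are clamped to
#' `-clamp_bound` whenever `median_g - lod_ct <= -clamp_bound`, i.e.
#' zero-expressers are assigned to the floor.
#'
#' @param ct A [ct_matrix()].
#' @param clamp_bound Absolute bound in cycles (default 5, i.e. 32-fold).
#' @param gene_medians Optional named vector of per-gene medians to centre
#'   on, e.g. from [pooled_gene_medians()] over several populations.  By
#'   default the medians of `ct` itself are used.
#' @return An [expression_matrix()].
#' @examples
#' ct <- ct_matrix(matrix(c(20, 22, 24), ncol = 1,
#'                        dimnames = list(NULL, "Actb")))
#' normalize_ct(ct)$values   # +2, 0, -2
#' @export
normalize_ct <- function(ct, clamp_bound = 5, gene_medians = NULL) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (length(ct$values) == 0) stop("cannot normalise an empty matrix")
  if (is.null(gene_medians)) {
    gene_medians <- apply(ct$values, 2, stats::median)
    names(gene_medians) <- ct$gene_ids
  } else {
    if (!all(ct$gene_ids %in% names(gene_medians)))
      stop("gene_medians must cover the gene panel")
    gene_medians <- gene_medians[ct$gene_ids]
  }
  e <- sweep(-ct$values, 2, -gene_medians)   # median - Ct
  e <- pmin(pmax(e, -clamp_bound), clamp_bound)
  expression_matrix(e, cell_ids = ct$cell_ids, gene_ids = ct$gene_ids,
                    clamp_bound = clamp_bound)
}

#' Drop genes with too many nondetects
#'
#' Optional gene filter: removes genes whose nondetect fraction exceeds
#' `max_nondetect_fraction`.  Off (fraction 1) by default; the pipeline keeps
#' nondetects at the floor value rather than excluding or imputing them.
#'
#' @param ct A [ct_matrix()].
#' @param max_nondetect_fraction Maximum tolerated fraction of nondetect
#'   cells per gene; genes above are dropped.
#' @return A filtered [ct_matrix()].
#' @export
filter_nondetect_genes <- function(ct, max_nondetect_fraction = 1) {
  frac <- colMeans(ct$values == ct$lod_ct)
  keep <- frac <= max_nondetect_fraction
  if (!any(keep)) stop("all genes exceed the nondetect threshold")
  ct[, which(keep)]
}

#' Write an expression matrix to a delimited table
#'
#' Values are printed with 17 significant digits so that a write/read
#' round-trip reproduces the doubles exactly.
#'
#' @param e An [expression_matrix()].
#' @param path Output path; `.csv` writes comma-separated, otherwise tabs.
#' @return Invisibly, the path.
#' @export
write_expression_table <- function(e, path) {
  stopifnot(inherits(e, "expression_matrix"))
  if (length(e$gene_ids) == 0 || length(e$cell_ids) == 0)
    stop("refusing to write an empty expression matrix")
  write_numeric_table(e$values, path)
  invisible(path)
}

#' Read an expression table written by [write_expression_table()]
#' @param path Path to the delimited table.
#' @param clamp_bound Clamp bound the values are expected to respect.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, clamp_bound = 5) {
  delim <- delim_for_path(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim, row.names = 1,
                           check.names = FALSE)
  expression_matrix(as.matrix(raw), clamp_bound = clamp_bound)
}

# Shared writer: ids + full-precision values, delimiter from extension.
write_numeric_table <- function(values, path) {
  delim <- delim_for_path(path)
  formatted <- matrix(sprintf("%.17g", values), nrow = nrow(values))
  out <- cbind(id = rownames(values), formatted)
  colnames(out) <- c("id", colnames(values))
  ok <- tryCatch({
    utils::write.table(out, path, sep = delim, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write table to ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Write a Ct matrix to a delimited table
#' @param ct A [ct_matrix()].
#' @param path Output path; `.csv` writes comma-separated, otherwise tabs.
#' @return Invisibly, the path.
#' @export
write_ct_table <- function(ct, path) {
  stopifnot(inherits(ct, "ct_matrix"))
  write_numeric_table(ct$values, path)
  invisible(path)
}
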