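# Seeded generator of synthetic single-cell qPCR mixtures.
#
# Emulates the phenomenology of single-cell qPCR panels: approximately
# Gaussian per-gene Ct distributions, a minority of genes with strongly
# left-skewed Ct laws (transcriptional bursts increase mRNA and so lower
# Ct), dropout pinned at the detection floor, and variability that shrinks
# with increasing expression.

#' Describe one subpopulation of a synthetic cell mixture
#'
#' @param weight Mixing probability of the subpopulation.
#' @param gene_means Named numeric vector of per-gene mean Ct values.
#' @param gene_sds Named numeric vector of per-gene Ct standard deviations
#'   (all > 0); recycled from length 1.
#' @param dropout_probs Per-gene probability that a reaction fails and is
#'   recorded at the detection floor; recycled from length 1, default 0.
#' @param burst_genes Subset of gene names drawn from a right-skewed
#'   (shifted log-normal) law instead of a Gaussian:
#'   `Ct = mean - LogNormal(0, burst_s)`, giving the left-tailed Ct
#'   asymmetry characteristic of bursty transcription.
#' @param burst_s Log-scale sigma of the burst law (default 1).
#' @return An object of class `subpop_spec`.
#' @export
subpop_spec <- function(weight, gene_means, gene_sds, dropout_probs = 0,
                        burst_genes = character(), burst_s = 1) {
  if (weight < 0 || weight > 1) stop("weight must lie in [0, 1]")
  genes <- names(gene_means)
  if (is.null(genes)) stop("gene_means must be a named vector")
  gene_sds <- rep_len(gene_sds, length(genes))
  dropout_probs <- rep_len(dropout_probs, length(genes))
  names(gene_sds) <- names(dropout_probs) <- genes
  if (any(gene_sds <= 0)) stop("gene_sds must be > 0")
  if (any(dropout_probs < 0 | dropout_probs > 1)) stop("dropout_probs must lie in [0, 1]")
  if (!all(burst_genes %in% genes)) stop("burst_genes must name genes in gene_means")
  structure(list(weight = weight, gene_means = gene_means, gene_sds = gene_sds,
                 dropout_probs = dropout_probs, burst_genes = burst_genes,
                 burst_s = burst_s),
            class = "subpop_spec")
}

#' Describe a synthetic mixture of cell subpopulations
#'
#' @param n_cells Number of cells to draw.
#' @param subpopulations List of [subpop_spec()] objects sharing a gene
#'   panel; weights must sum to 1 (tolerance 1e-9).
#' @param seed Integer seed making the draw reproducible.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_cells, subpopulations, seed = 1) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (inherits(subpopulations, "subpop_spec")) subpopulations <- list(subpopulations)
  w <- vapply(subpopulations, function(s) s$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) stop("subpopulation weights must sum to 1")
  genes <- names(subpopulations[[1]]$gene_means)
  for (s in subpopulations)
    if (!identical(names(s$gene_means), genes))
      stop("all subpopulations must share one gene panel")
  structure(list(n_cells = as.integer(n_cells), subpopulations = subpopulations,
                 seed = seed),
            class = "population_spec")
}

#' Simulate a single-cell qPCR Ct matrix from a mixture specification
#'
#' Each cell's subpopulation is drawn from the mixture weights; each gene
#' value from that subpopulation's Gaussian (or burst) Ct law; then with the
#' gene's dropout probability the reaction is replaced by the detection
#' floor `lod_ct`.  All values are clipped to `(0, lod_ct]`.  The same seed
#' always yields the same output.
#'
#' @param spec A [population_spec()].
#' @param lod_ct Detection floor in cycles (default 40).
#' @param population_label Label stored on the resulting matrix.
#' @return A list with elements `ct` (a [ct_matrix()]) and `labels`
#'   (integer subpopulation index per cell).
#' @export
simulate_cells <- function(spec, lod_ct = 40, population_label = "synthetic") {
  stopifnot(inherits(spec, "population_spec"))
  genes <- names(spec$subpopulations[[1]]$gene_means)
  n <- spec$n_cells
  g <- length(genes)
  with_seed(spec$seed, {
    w <- vapply(spec$subpopulations, function(s) s$weight, numeric(1))
    labels <- sample.int(length(w), n, replace = TRUE, prob = w)
    vals <- matrix(NA_real_, n, g, dimnames = list(sprintf("cell%03d", seq_len(n)), genes))
    for (s_idx in seq_along(spec$subpopulations)) {
      rows <- which(labels == s_idx)
      if (!length(rows)) next
      s <- spec$subpopulations[[s_idx]]
      for (j in seq_len(g)) {
        gene <- genes[j]
        m <- length(rows)
        draw <- if (gene %in% s$burst_genes) {
          s$gene_means[[gene]] - stats::rlnorm(m, 0, s$burst_s)
        } else {
          stats::rnorm(m, s$gene_means[[gene]], s$gene_sds[[gene]])
        }
        drop <- stats::runif(m) < s$dropout_probs[[gene]]
        draw[drop] <- lod_ct
        vals[rows, j] <- draw
      }
    }
    vals <- pmin(pmax(vals, 0.01), lod_ct)
    list(ct = ct_matrix(vals, population_label = population_label, lod_ct = lod_ct),
         labels = labels)
  })
}

# Three archetype subpop_specs over a shared gene panel.  Each signal gene
# takes a distinct mean in every archetype (offsets 0 / -shift / -2*shift in
# a gene-dependent permutation), so any change in mixture weights changes
# every signal gene's marginal distribution; noise genes have one shared law
# in every archetype so only mixture weights differ between populations
# built from these archetypes.
make_archetypes <- function(gene_means, gene_sds, dropout_probs, signal_genes,
                            burst_genes, shift, weights) {
  perms <- list(c(0, 1, 2), c(1, 2, 0), c(2, 0, 1),
                c(0, 2, 1), c(2, 1, 0), c(1, 0, 2))
  lapply(seq_along(weights), function(a) {
    m <- gene_means
    for (j in seq_along(signal_genes)) {
      perm <- perms[[(j - 1) %% length(perms) + 1]]
      m[signal_genes[j]] <- m[signal_genes[j]] - shift * perm[a]
    }
    subpop_spec(weights[a], m, gene_sds, dropout_probs, burst_genes)
  })
}

#' Generate a three-population synthetic study fixture
#'
#' Builds three 300-cell, 43-gene Ct matrices sharing the same three
#' subpopulation archetypes but mixed with different occupancy weights:
#' an evenly mixed reference population (`cd34lo`, weights 1/3 each), a
#' population nearly lacking archetype 1 (`cd34hi`, weights 0.04 / 0.58 /
#' 0.38), and a population enriched for archetype 1 (`sp`, weights 0.68 /
#' 0.16 / 0.16).  Nine of the 43 genes are "signal" genes taking a
#' distinct mean in each archetype (offsets of 0, `-shift` and `-2 shift`
#' cycles in gene-dependent permutations), so every signal gene's marginal
#' distribution responds to any change in mixture weights; the remaining 34
#' share one law across archetypes, three of them bursty.  Per-gene standard
#' deviations increase with mean Ct so that relative variability falls with
#' increasing expression.
#'
#' @param seed Integer seed.
#' @param n_cells Cells per population (default 300).
#' @param shift Between-archetype mean shift on signal genes, in cycles
#'   (default 3, comfortably above the 2-cycle detectability scale).
#' @return A list with `ct_matrix` elements `cd34lo`, `cd34hi`, `sp`;
#'   `labels` (list of true archetype indices per population); `signal_genes`;
#'   `weights` (list of generating occupancy vectors); and `archetypes`.
#' @export
make_study_fixture <- function(seed = 1, n_cells = 300, shift = 3) {
  genes <- c("Mycn", "Cdkn2a", "Tal1", "Ccnd1", "Rbl1", "Gata2", "Meis1",
             "Hoxb4", "Cdkn1a",                       # signal genes
             "Actb", "Ptprc", "Runx1", "Myb",
             sprintf("g%02d", 14:43))
  signal_genes <- genes[1:9]
  sub_seeds <- derive_seeds(seed, 4)
  gene_means <- with_seed(sub_seeds[1], {
    m <- stats::runif(length(genes), 16, 31)
    names(m) <- genes
    m[signal_genes] <- stats::runif(9, 18, 24)
    m
  })
  # variability shrinks with expression: later detection -> larger sd
  gene_sds <- 0.6 + 0.04 * (gene_means - 14)
  # dropout follows a logistic link to mean Ct: negligible for strongly
  # expressed genes, appreciable near the detection limit
  dropout_probs <- stats::plogis((gene_means - 33) / 1.5)
  burst_genes <- c("Tal1", "Ccnd1", "g20", "g27", "g35")
  burst_genes <- setdiff(burst_genes, signal_genes)   # bursts stay non-differential
  weights <- list(cd34lo = c(1, 1, 1) / 3,
                  cd34hi = c(0.04, 0.58, 0.38),
                  sp     = c(0.68, 0.16, 0.16))
  pops <- lapply(seq_along(weights), function(p) {
    arche <- make_archetypes(gene_means, gene_sds, dropout_probs, signal_genes,
                             burst_genes, shift, weights[[p]])
    spec <- population_spec(n_cells, arche, seed = sub_seeds[p + 1])
    sim <- simulate_cells(spec, population_label = names(weights)[p])
    sim
  })
  names(pops) <- names(weights)
  list(cd34lo = pops$cd34lo$ct, cd34hi = pops$cd34hi$ct, sp = pops$sp$ct,
       labels = lapply(pops, `[[`, "labels"),
       signal_genes = signal_genes,
       weights = weights,
       archetypes = make_archetypes(gene_means, gene_sds, dropout_probs,
                                    signal_genes, burst_genes, shift,
                                    weights$cd34lo))
}

#' Generate a compact well-separated k-subpopulation fixture
#'
#' A small panel (default 9 genes) in which each gene is expressed `shift`
#' cycles higher in one of `k` archetypes (genes assigned to archetypes in
#' round-robin), with unit within-subpopulation standard deviation and no
#' dropout.  With `k = 1` the result is a homogeneous Gaussian population.
#'
#' @param seed Integer seed.
#' @param k Number of subpopulations (default 3).
#' @param n_cells Total cells (default 300).
#' @param n_genes Panel size (default 9).
#' @param shift Between-subpopulation mean shift in cycles (default 2).
#' @param sd Within-subpopulation Ct standard deviation (default 1).
#' @return As [simulate_cells()]: a list with `ct` and `labels`.
#' @export
make_separated_fixture <- function(seed = 1, k = 3, n_cells = 300, n_genes = 9,
                                   shift = 2, sd = 1) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  base <- stats::setNames(rep(22, n_genes), genes)
  subs <- lapply(seq_len(k), function(a) {
    m <- base
    block <- genes[((seq_len(n_genes) - 1) %% k) + 1 == a]
    m[block] <- m[block] - shift
    subpop_spec(1 / k, m, sd)
  })
  simulate_cells(population_spec(n_cells, subs, seed = seed))
}
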