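---
title: "Transcriptional fingerprinting of single-cell qPCR panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptional fingerprinting of single-cell qPCR panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctfingerprint)
```

## The question the package answers

A tightly FACS-sorted cell population — the motivating case is murine
long-term hematopoietic stem cells assayed on 48.48 microfluidic qPCR
arrays — looks homogeneous by surface phenotype, yet single-cell
measurements show large cell-to-cell transcriptional variation.  Is that
variation pure stochastic noise around one expression program, or does the
population mix several discrete subpopulations?  ctfingerprint operationalises
the question as model selection: a population is called homogeneous when a
one-cluster model loses less information (in the Kullback–Leibler sense
estimated by AICc) than every multi-cluster alternative, and heterogeneous
when some soft k-cluster partition wins.

## Data model and normalisation

The raw datum is a cells × genes matrix of qPCR cycle thresholds (Ct).  One
cycle is one template doubling, so Ct is an inverse log2 scale for mRNA:
lower Ct means more transcript.  Reactions that fail to amplify within 40
cycles are nondetects, stored exactly at the detection floor
(`lod_ct = 40`).  Nondetects stay in every downstream computation as floor
values; nothing is imputed or dropped by default (an optional
`filter_nondetect_genes()` exists for panels with genes that fail in most
cells, off by default because the motivating analysis clustered on the full
clamped matrix).

`normalize_ct()` maps Ct to expression as

    e[i, g] = clamp(median_g(Ct) - Ct[i, g], -B, +B),    B = 5 cycles

with the median taken over the pooled sample of all cells under analysis
(per-population medians are available via the `gene_medians` argument).
The sign convention is chosen so that **higher values mean more mRNA**; the
±5-cycle clamp corresponds to a 32-fold bound on fold change from the
median, and nondetects land at the −5 floor for any gene whose pooled
median is below 35 cycles.  With an even number of cells the median is the
mean of the two central order statistics.

## Variability statistics

`gene_cov()` is the sample coefficient of variation sd/mean (n−1
denominator), and `multivariate_cov()` its pooled generalisation over a
gene set, `sqrt(sum of variances) / sqrt(sum of squared means)` (the Van
Valen form), a scale-invariant dispersion index.  Because the COV needs a
positive scale, it is computed on raw Ct values or on linear expression
`2^e`; for a median-centred log2 matrix (means near zero) the univariate
COV is not meaningful and `select_top_cov_genes()` therefore converts such
input to the linear scale first.  `bootstrap_cov_sd()` attaches a
resampling standard error (default 100,000 resamples; the test suite uses
10,000 and checks it against exhaustive enumeration of all resamples at
n = 5).

## Gene selection

`select_differential_genes()` compares the two populations gene-by-gene
with the two-sample Kolmogorov–Smirnov statistic and applies a Bonferroni
correction (`p_adjusted = min(1, p × n_tests)`, `n_tests` defaulting to the
panel size), selecting genes with `p_adjusted < 0.01`.  Asymptotic rather
than exact p-values are used deliberately: Ct data carry heavy ties at the
detection floor and at the clamp, which invalidate the exact no-ties
formulas; a message notes when the tie fraction exceeds 5%.  Selection runs
on the normalised (clamped) matrices, matching the pipeline order; raw-Ct
testing is possible by passing `ct_matrix` objects directly.

## Fuzzy clustering

`fcm_fit()` implements standard fuzzy c-means: memberships
`u_ij = 1 / sum_l (d_ij/d_il)^(2/(m-1))`, weighted-mean centroids
`c_j = sum_i u_ij^m x_i / sum_i u_ij^m`, objective
`J_m = sum u_ij^m d_ij^2`.  Design choices worth knowing:

* **Initialisation.** Each of `n_restarts` (default 20) runs seeds
  centroids by k-means++-style sampling over cells, then pulls the seeds 5%
  toward the global mean.  The pull matters: a centroid placed exactly on a
  data point is an absorbing state under the rule that a coincident cell
  receives full membership (its weight `u^m = 1` dominates every other
  cell's at large `m`), which we found via the m → ∞ uniformity property.
* **Numerical form of the membership update.** Ratios are taken to the
  row-minimum distance so every term lies in [0, 1]; at small fuzziness
  (m = 1.05 gives exponent 40) the naive `1/d^40` form overflows.
* **Convergence.** Relative objective change or maximum membership change
  below `tol = 1e-6`, capped at `max_iter = 1000`; non-convergence returns
  the model flagged `converged = FALSE` with a warning.
* **Metrics.** Euclidean (default), Manhattan, and Minkowski of any order
  p ≥ 1.  For non-Euclidean metrics the weighted-mean centroid update is
  retained (drop-in metric substitution, as commonly implemented) rather
  than the metric-specific minimiser; descent of the objective is then not
  guaranteed, so the in-loop monotonicity warning applies only to the
  Euclidean case.  This is documented as an approximation.
* **Hard assignment.** Argmax membership, ties broken toward the lowest
  cluster index (reported via a message).

`kmeans_fit()` wraps `stats::kmeans` into the same `cluster_model`
container (0/1 memberships), and `project_population()` evaluates the FCM
membership formula on new cells with centroids **fixed** — no refitting —
which is how additional populations are placed into the reference
partition to yield occupancy tables.  `partition_agreement()` is the
adjusted Rand index of the hardened partitions (via mclust).

## Likelihood, AICc, and the (k, m) grid

The central interpretive choice of the package is how a likelihood attaches
to a fuzzy partition.  `score_model()` reads the memberships as mixture
responsibilities of a spherical Gaussian mixture: mixing weights are mean
memberships, a single pooled variance is `sigma2 = sum u_ij d_ij^2 / (n g)`
(Euclidean distances), and

    logL = sum_i log sum_j pi_j N(x_i; c_j, sigma2 I)
    K    = k g + (k - 1) + 1
    AIC  = -2 logL + 2 K,    AICc = AIC + 2K(K+1)/(n - K - 1)

This form was adopted because it reduces exactly to the closed-form
spherical-Gaussian fit at k = 1 (verified against the analytic expression
in the tests), varies smoothly with the fuzziness through `u`, and yields
interior optima in (k, m).  The fuzziness coefficient is treated as a
selected hyperparameter, not a counted parameter: counting it would add a
constant 2 across the m-grid and cannot change the argmin in m.  The AICc
sample size is the number of cells (not cells × genes), a conservative
choice.  When `n <= K + 1` the correction is undefined and the grid point
is skipped with a warning.

`optimize_grid()` fits every point of a `model_grid()` (defaults k = 1..6,
m = 1.05 to 3.00 by 0.05 — the low end is included so near-hard optima are
representable; k = 1 is m-independent and scored once) and reports AICc
differences, Akaike weights `w_i = exp(-delta_i/2)/sum exp(-delta_l/2)`,
and evidence ratios `w_best/w_i`.  Ties break toward smaller k, then
smaller m (parsimony first).

## Stability diagnostics

* `bootstrap_cluster_number()`: repeats the full grid search on subsets of
  cells (default 70%, sampled **without** replacement — "subsets of
  distinct cells"; a `replace = TRUE` flag gives the classical bootstrap)
  and tabulates the winning k.  The full grid is re-optimised per subset
  (conservative); m can be fixed by passing a one-value m-grid.
* `prediction_strength()`: Tibshirani–Walther cross-validated validity with
  k-means (the simplest partitional baseline, deliberately not FCM): train
  and test folds are clustered separately, test cells are classified by
  nearest training centroid, and ps(k) is the minimum over test clusters of
  the fraction of within-cluster test pairs co-assigned by the training
  classifier; chosen k is the largest with mean ps above 0.8.  Test
  clusters of size < 2 contribute 1 by convention.
* `gene_panel_sensitivity()`: re-optimises on alternative gene panels and
  reports each panel's best (k, m) and adjusted Rand index against the
  first (reference) panel.

## The synthetic-data generator

No single-cell dataset ships with the package, so `simulate_cells()` plus
`make_study_fixture()` provide seeded data with known truth.  The
generator emulates four features of single-cell qPCR panels: approximately
Gaussian per-gene Ct distributions; a minority of "bursty" genes drawn
from `Ct = mean - LogNormal(0, s)` (s = 1 by default), giving the
left-tailed Ct asymmetry of transcriptional bursts; dropout that replaces a
reaction by the Ct = 40 floor, with per-gene probability following a
logistic link to mean Ct (`plogis((mean - 33)/1.5)`: negligible for
strongly expressed genes, ~20% near Ct 31) — an expression-independent
probability can be supplied instead; and per-gene standard deviations that
rise with mean Ct (`0.6 + 0.04 (mean - 14)` cycles), so relative
variability falls with increasing expression.

`make_study_fixture()` builds the three-population study design: 300
cells × 43 genes per population, three shared subpopulation archetypes
mixed at (1/3, 1/3, 1/3) in the reference (`cd34lo`), (0.04, 0.58, 0.38)
in the comparison (`cd34hi`), and (0.68, 0.16, 0.16) in the enriched
population (`sp`).  Nine signal genes take a distinct mean per archetype
(offsets 0 / −3 / −6 cycles in gene-dependent permutations).  The offsets
are permuted rather than block-assigned on purpose: a gene marking only one
archetype whose weight barely changes between populations (1/3 → 0.38) has
an almost unchanged marginal distribution and is undetectable by any
two-sample test; with permuted offsets every signal gene responds to every
weight change.  The remaining 34 genes share one law across archetypes
(three of them bursty), so between-population differences exist only where
the design says they do.

What the generator does **not** emulate: gene–gene covariation within a
subpopulation (genes are conditionally independent), PCR efficiency and
pre-amplification bias, cell-cycle structure, and kinetic (telegraph-model)
burst dynamics.  Passing tests on this fixture therefore demonstrate that
the machinery recovers planted mixture structure under realistic marginals
— not that any particular biological dataset contains such structure.

## Problem sizes and reproducibility

Every stochastic function takes an explicit integer seed and derives
per-stage sub-seeds from it; identical seeds give bit-identical results,
and pipeline artifacts are byte-reproducible.  The package defaults are the
full analysis settings (m-grid step 0.05, 20 restarts, 100,000 COV
resamples, 100 prediction-strength iterations).  The test suite and the
acceptance script run the same code at desk scale — m-grid
{1.05, 1.5, 2, 2.5, 3} with 3 restarts for the repeated-recovery loops, 50
bootstrap subsets, 20 prediction-strength iterations, 10,000 COV resamples
— sizes at which every qualitative conclusion is already stable (e.g.
doubling the COV resample count moves the bootstrap sd by under 2%).

## Known limitations

* The Gaussian pseudo-likelihood is an interpretive bridge from fuzzy
  partitions to information criteria, not a generative model fit by
  maximum likelihood; its parameter count is a convention (documented
  above), so AICc values are comparable within a grid, not across datasets.
* Clamp piles (many cells at exactly ±5) and heavy-tailed bursty genes can
  genuinely support extra small clusters; on panels chosen by raw
  variability (top-COV) the optimal k can exceed the number of planted
  archetypes.  This is a property of the data representation, not a bug;
  the KS-selected panel is the intended clustering substrate.
* Bonferroni control is conservative with 43 correlated tests; a
  Benjamini–Hochberg alternative is available via
  `select_differential_genes(..., method = "BH")`, but the selection
  contract of this package is family-wise.
* Non-Euclidean centroid updates are approximate (see above); Minkowski
  orders far from 2 should be read as sensitivity analyses, not as exact
  optimisers.
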