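# ctfingerprint

Information-theoretic analysis of single-cell qPCR panels: does a sorted
cell population harbour discrete transcriptional subpopulations, or is its
cell-to-cell variability just noise around one expression program?

The motivating setting is microfluidic single-cell qPCR (48.48 dynamic
arrays, 2,304 reactions per chip run) applied to putatively homogeneous
stem-cell fractions: hundreds of cells, a ~43-gene panel, cycle-threshold
(Ct) readout with nondetects pinned at Ct = 40.  ctfingerprint implements the
full analysis path for such data:

1. **Normalisation** — per-gene pooled-median centring of Ct, converted to
   log2 fold change (`e = median − Ct`, higher = more mRNA) and clamped to
   ±5 cycles (a 32-fold bound); nondetects sit at the −5 floor.
2. **Variability** — univariate and pooled (Van Valen) coefficients of
   variation with bootstrap standard errors.
3. **Gene selection** — per-gene two-sample Kolmogorov–Smirnov tests
   between populations with Bonferroni control (`p_adjusted < 0.01`), or
   alternatively the top-COV genes.
4. **Soft partitioning** — fuzzy c-means under Euclidean, Manhattan or
   Minkowski distances, with membership matrix `u_ij` and fuzziness
   coefficient `m > 1` (`m → 1` recovers k-means).
5. **Model selection** — an exhaustive grid over cluster number `k` and
   fuzziness `m`, scored by a Gaussian-mixture pseudo-likelihood and AICc
   (`AIC = −2 logL + 2K`, second-order small-sample correction), reported
   with AIC differences, Akaike weights and evidence ratios.
6. **Projection** — new populations are placed onto the *fixed* reference
   centroids and summarised as per-cluster occupancy fractions.
7. **Stability** — bootstrap distribution of the optimal `k` over 70%
   cell subsets, Tibshirani–Walther prediction strength (five-fold CV,
   threshold 0.8), and gene-panel / metric sensitivity (adjusted Rand
   index).

Because the motivating 300-cell dataset is not publicly deposited, the
package ships a seeded synthetic generator (`simulate_cells()`,
`make_study_fixture()`) that reproduces the statistical structure of
such panels — Gaussian Ct marginals, left-skewed "bursty" genes, dropout
at the detection floor, variability shrinking with expression — with known
ground truth, so every stage is testable end to end.

## Worked example

```r
library(ctfingerprint)

fx  <- make_study_fixture(seed = 1)          # cd34lo / cd34hi / sp trio
med <- pooled_gene_medians(list(fx$cd34lo, fx$cd34hi, fx$sp))
e   <- lapply(list(cd34lo = fx$cd34lo, cd34hi = fx$cd34hi, sp = fx$sp),
              normalize_ct, gene_medians = med)

ks    <- select_differential_genes(e$cd34lo, e$cd34hi)   # KS + Bonferroni
panel <- ks$gene[ks$selected]

opt <- optimize_grid(e$cd34lo[, panel],
                     model_grid(1:6, c(1.05, 1.5, 2, 2.5, 3)),
                     n_restarts = 3, seed = 2)
head(model_selection_report(opt$scores), 4)
#>   k    m     aicc delta_aic akaike_weight evidence_ratio
#> 1 3 1.05 7330.412   0.00000  9.876291e-01   1.000000e+00
#> 2 3 1.50 7339.934   9.52237  8.449627e-03   1.168843e+02
#> 3 4 1.05 7341.470  11.05777  3.921289e-03   2.518634e+02
#> 4 4 1.50 7366.781  36.36898  1.250752e-08   7.896285e+07

for (pop in names(e)) {
  proj <- project_population(opt$best, e[[pop]][, panel])
  cat(sprintf("%-7s occupancy: %s\n", pop,
      paste(sprintf("%.1f%%", 100 * proj$occupancy$fractions), collapse = " / ")))
}
#> cd34lo  occupancy: 35.7% / 35.0% / 29.3%
#> cd34hi  occupancy: 36.7% / 58.3% / 5.0%
#> sp      occupancy: 16.0% / 13.3% / 70.7%
```

Reading the output: the KS step recovers the 9 planted signal genes; the
AICc trough sits at three clusters with fuzziness 1.05 (the Akaike weight
of the best model is 0.99, and the evidence ratio against the next
configuration is ~117); and projection onto the fixed centroids shows the
third cluster nearly absent from the cd34hi population (5%, generating
weight 4%) and dominant in the sp population (70.7%, generating weight
68%) — exactly the planted occupancy shifts, each within multinomial
sampling error at n = 300.

A full pipeline run (normalise → select → optimise → project → export)
with a JSON manifest of artifacts is available as `run_pipeline()` /
`run_config()`, or from the shell:

```sh
exec/ctfingerprint run --config cfg.yaml
exec/ctfingerprint simulate --seed 1 --out-prefix sim   # other subcommands:
exec/ctfingerprint optimize --input sim_cd34lo.csv      # cov, select,
                                                        # cluster, stability, order
```

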