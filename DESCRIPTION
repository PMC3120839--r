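Package: ctfingerprint
Title: Information-Theoretic Clustering of Single-Cell qPCR Transcriptional Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-cell quantitative PCR (qPCR)
    cycle-threshold matrices: median-based normalisation with detection-floor
    handling, coefficient-of-variation statistics with bootstrap standard
    errors, Kolmogorov-Smirnov differential-distribution gene selection,
    fuzzy c-means clustering under pluggable distance metrics with
    AICc-driven selection of the cluster number and fuzziness coefficient,
    projection of new cell populations onto fixed centroids, and
    bootstrap / prediction-strength cluster-stability diagnostics.  A seeded
    synthetic-data generator emulates the statistical structure of
    single-cell qPCR mixtures so the full pipeline can be exercised and
    tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
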