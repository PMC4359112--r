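Package: sparcoc
Title: Common-Background Sparse-Foreground Decomposition and Checkerboard
    Co-Clustering for Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Unsupervised molecular-subtype discovery for genes-by-samples
    expression matrices.  An alternating direction method of multipliers
    (ADMM) solver decomposes a matrix into a rank-one common background
    (a shared per-gene expression baseline), a sparse foreground of
    gene-by-sample deviations, and a Frobenius-bounded noise term; a
    multi-condition variant replaces the rank-one background with a
    nuclear-norm-penalized low-rank background shared across conditions.
    The sparse foreground is then checkerboard co-clustered into row
    (gene) and column (sample) groups by the Maximum Block Improvement
    (MBI) block-coordinate method, with consensus aggregation over
    stochastic restarts.  Downstream utilities cover per-gene Welch
    t-test signature selection, signature intersection and filtering,
    least-squares (nearest-centroid) sample classification, Kaplan-Meier
    estimation and two-group log-rank survival comparison, plus planted
    checkerboard simulators and CSV readers/writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
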