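Package: stagewiseFDR
Title: Stage-Wise Testing for Gene-Level False Discovery Rate Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage (screening and confirmation) hypothesis testing for
    transcriptomics experiments in which several hypotheses are tested per
    gene, controlling the overall false discovery rate (OFDR) at the gene
    level. The screening stage tests a per-gene omnibus null with
    Benjamini-Hochberg FDR control; the confirmation stage tests the
    individual hypotheses of screened genes with within-gene family-wise
    error control by Holm or Shaffer's modified sequentially rejective
    Bonferroni procedure, exploiting the logical constraints of differential
    gene expression, differential transcript expression and differential
    transcript usage designs. Includes gene-level aggregation of
    transcript-level p-values, reference procedures for benchmarking
    (per-contrast BH and the Jiang-Doerge two-stage method),
    negative-binomial count simulators for factorial and transcript-level
    designs, a minimal per-feature testing engine, and evaluation metrics
    (FDP/TPR curves, OFDR estimation, false-positive decomposition).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
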