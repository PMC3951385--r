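Package: qpcrstab
Title: Reference Gene Stability Analysis for RT-qPCR Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for validating candidate reference
    (housekeeping) genes for RT-qPCR normalization. Converts raw
    amplification fluorescence traces or Ct tables into
    efficiency-corrected starting quantities (R0 = R_Ct * (1+E)^-Ct),
    screens technical replicates for outlying amplification
    efficiencies, ranks candidate reference genes with both the
    iterative pairwise-variation stability measure (geNorm-style M
    values and the V_n/V_n+1 rule for the optimal number of reference
    genes) and a model-based intra-/inter-group variance decomposition
    (NormFinder-style stability values), builds geometric-mean
    normalization factors, normalizes target genes, and quantifies the
    impact of alternative reference-gene choices. Includes a synthetic
    qPCR experiment generator with known ground truth emulating a
    multi-tissue, multi-stress plant study design, so every stage is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
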