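Package: rhizoprot
Title: Cross-Species Seasonal Rhizome Proteomics and Convergence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative cross-species proteomics of perennial
    grass rhizomes sampled across seasons. Implements total-peptide-amount
    normalization, per-species seasonal differential protein abundance
    (one-way ANOVA with a Tukey HSD season contrast, optional additive
    batch/year adjustment, Benjamini-Hochberg correction), orthogroup-level
    fold-change aggregation and cross-species convergence statistics
    (Spearman correlation, exclusive-class co-occurrence counts, top-N
    selection), a tiered peptide-evidence reassignment scheme for re-homing
    proteins quantified against a mismatched reference proteome,
    keyword-based binning of proteins into cold-related functional
    categories with a chi-square homogeneity test, and sequence-level
    analysis of group-3 late embryogenesis abundant (LEA3) proteins:
    Dure 11-mer motif detection, sliding-window hydropathy profiles and
    quantitative amphipathic-pattern comparison between orthologs.
    Ships simulators that generate abundance matrices, motif-bearing
    proteomes and peptide hit tables with known ground truth, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
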