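Package: toppreserve
Title: Compositional-Bias, Interactome and TOP mRNA Maintenance Statistics for
    Splice-Isoform Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for studies of arginine-glycine (RG/RGG) rich
    splice isoforms of RNA-binding proteins and their role in preserving 5'
    terminal oligopyrimidine (TOP) mRNAs during nutrient starvation. Provides
    dipeptide compositional-bias statistics with exact-binomial and permutation
    nulls, right-sided Fisher's exact tests for regional motif enrichment,
    RG/RGG motif scanning, per-column conservation scoring of multiple sequence
    alignments with an exact Mann-Whitney region test, a label-free IP-MS
    differential-enrichment pipeline (detection filtering, downshifted-normal
    imputation, Student's t with Benjamini-Hochberg FDR, geometric-mean fold
    changes, interactor calling), downstream analysis of differential-expression
    tables (DEG classification, gene-set overlap with representation factors,
    TOP/ribosomal-protein maintenance reports), spike-in normalized
    delta-delta-Ct quantification with RIP and densitometry corrections, and
    seeded synthetic-data generators that emulate the statistical structure of
    each input, including the equal-mass library normalization artifact that
    makes per-cell-maintained transcripts appear up-regulated.
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
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
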