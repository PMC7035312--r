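Package: scsperm
Title: Single-Sperm scRNA-seq QC, Differential Expression, and
    Cell-Resolved Variant Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for single-spermatozoon RNA-seq:
    quality-control filtering of barcoded UMI count matrices (UMI, gene,
    and mitochondrial-fraction thresholds), single-cell-level Wilcoxon
    rank-sum differential expression with Bonferroni adjustment and an
    expression-fraction marker filter, a transparent haploid
    variant caller operating on cell-barcode-resolved pileups from
    barcoded alignments, and bulk-level variant post-processing
    (SNP-cluster and alternative-depth hard filters, genomic-region
    classification, rare-variant filtering against a population
    allele-frequency table) with mapped-base-normalized variant-burden
    statistics and a one-sided rank-sum cohort comparison. A synthetic-data
    module generates barcoded count matrices, alignments, annotations and
    allele-frequency tables with known planted truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    Rsamtools,
    vcfR,
    data.table,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
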