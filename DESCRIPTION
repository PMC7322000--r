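Package: repeatscreen
Title: Quantifying Retrotransposon Silencing: Repeat ChIP Enrichment,
    Repeat RNA Expression, and Methylation-Dependent Interaction Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A verifiable pipeline for the three quantitative readouts used
    to study DNA-methylation-directed silencing of retrotransposons:
    (1) a methylation-dependent protein-interaction screen on two-condition
    unique-peptide-count tables with a pseudocounted ratio statistic and
    display/hit filters; (2) ChIP-seq enrichment of repeat families and
    imprinting control regions (treatment cpm over control cpm after
    duplicate removal) plus an LTR-anchored metaprofile with a 5'/3' LTR
    contrast; and (3) repeat-family RNA expression quantification (FPKM,
    background adjustment by the pooled DNA-transposon signal, rescaling to
    cpm) with median-of-ratios-normalized log2 fold changes and reactivation
    calls. A synthetic-data generator plants known enrichments, fold changes
    and proteomic hits in a toy genome so that every stage is testable by
    parameter recovery at desk scale.
License: MIT
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
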