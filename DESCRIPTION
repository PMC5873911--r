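Package: tumorGI
Title: Genome Instability Analysis for Serially Allografted Tumor Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Coverage-based copy-number analysis and somatic point-mutation
    statistics for tumor/host paired whole-genome sequencing, aimed at
    serially allografted Drosophila larval brain tumors where the matched
    control is polytene larval tissue. Implements GC-bias correction of
    binned coverage via a Tweedie generalized additive model, mappability
    and GC filtering, cross-sample quantile normalization, circular binary
    segmentation of tumor/control log ratios with permutation p-values and
    an SD-based merge rule, five-state copy-number calling with
    under-replicated-region masking, coverage-based sex inference, CNV
    catalog summaries and passage-to-passage turnover, and somatic SNP
    analyses (six-class substitution spectrum, binomial clustering and
    region-enrichment tests, exome mutation rates, read-orientation
    oxidation-artifact checks). A synthetic-data generator reproduces the
    statistical structure of the assay, including polytene
    under-replication of the control and lesion birth/retention dynamics
    across transplantation rounds, for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    limma,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
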