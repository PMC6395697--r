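Package: methylscape
Title: Multi-Layer Methylome Analysis of Two-Group Synoviocyte Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for comparative analysis of whole-genome
    bisulfite sequencing methylomes from two-group cohorts (e.g. rheumatoid
    arthritis versus osteoarthritis synoviocytes), together with the
    expression, miRNA and exome layers that surround them. Provides methylome
    segmentation into partially methylated domains (PMDs), unmethylated
    regions (UMRs) and low-methylated regions (LMRs) via a symmetric-Beta
    polarization score and a two-state Gaussian hidden Markov model;
    disease-specific LMR calling, profiling and clustering; single-CpG
    differential (logistic-regression) and variability (Levene) statistics
    with overlap and classification analyses; GSEA-style enrichment of
    LMR-proximal genes in expression rankings; miRNA-methylation and
    miRNA-target correlation; and a Poisson mutation-excess test for
    rare-variant burden. A fully seeded synthetic cohort generator with
    complete ground truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    Rcpp,
    IRanges,
    GenomicRanges,
    S4Vectors,
    DESeq2,
    SummarizedExperiment,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
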