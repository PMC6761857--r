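Package: sweepscan
Title: Selective-Sweep Scans from Sparse Genotyping Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for detecting candidate signatures of
    positive selection in livestock cohorts genotyped by reduced
    representation sequencing. Implements VCF hard filtering with
    per-stage accounting and Ts/Tv reporting, marker- and sample-level
    genotype quality control (minor allele frequency, call rate, LD
    pruning, identity-by-state duplicate detection), per-individual
    heterozygosity and inbreeding, SNP-based relatedness (the unadjusted
    Ajk estimator), Evanno delta-K post-processing of clustering
    likelihoods, pooled-heterozygosity (Hp/ZHp) sliding-window sweep
    scans, windowed Weir-Cockerham Fst between two cohorts with
    empirical-tail significance and region merging, and candidate-region
    gene annotation. A Balding-Nichols synthetic-cohort generator with
    implanted sweep and differentiation regions provides ground truth for
    end-to-end testing without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    optparse,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
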