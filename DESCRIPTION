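Package: flaxnue
Title: Genetic Dissection of Nitrogen Use Efficiency Traits by Multi-Locus
    GWAS, Expression Colocalization and Genomic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for dissecting the genetic
    architecture of nitrogen use efficiency (NUE) seedling traits in inbred
    crop panels such as flax. Derives 21 NUE-related traits (treatment
    ratios, stress tolerance index) from replicate-level measurements under
    optimum and deficient nitrogen; estimates linkage disequilibrium decay,
    IBS kinship and the VanRaden genomic relationship matrix; runs a
    two-stage multi-locus mixed-model GWAS (EMMA-style REML null, P3D
    screen, extended-BIC multi-marker refinement, LOD-scored QTNs);
    validates QTNs by Mann-Whitney allele-effect tests and merges them into
    LD-based QTL blocks; tests differential expression with per-gene
    negative-binomial GLMs and colocalizes DEGs within QTL windows; and
    compares GWAS-derived marker sets against genome-wide markers for GBLUP
    genomic prediction under repeated cross-validation. A seeded
    synthetic-data generator (genotypes with block LD and population
    structure, correlated phenotypes with planted QTLs, negative-binomial
    counts with planted fold changes, gene annotations) makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    minpack.lm,
    vcfR,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
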