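Package: DRmismatch
Title: Multiscale Donor-Recipient Genetic Mismatch Analysis for Transplant Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies non-HLA genetic mismatch between organ donors and
    recipients at variant, gene, haplotype, and genome-wide scales from
    imputed genotype data, and screens the resulting mismatch scores for
    association with death-censored graft loss. Provides quality control for
    imputed genotypes (missingness, minor allele frequency, Hardy-Weinberg
    exact test, imputation quality, MHC exclusion), IQR-normalized mismatch
    scores, pairwise identity-by-descent estimation, LD-based haplotype block
    construction with mismatch dosage and directionality classification,
    proportional-hazards screening under multiple scenarios, additive-model
    cis-eQTL and seed-gene coexpression analysis, and a fully seeded
    synthetic-cohort generator so the complete pipeline is testable without
    access to protected cohort genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Genetics, SNP, Transplantation, Survival, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'DRmismatch-package.R'
    'accessors.R'
    'association.R'
    'eqtl.R'
    'genotype-io.R'
    'haplotype.R'
    'mismatch.R'
    'pipeline.R'
    'simulate.R'
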