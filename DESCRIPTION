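Package: famEWAS
Title: Family-Based Epigenome-Wide Association Analysis of Age-Related DNA
    Methylation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Kinship-aware epigenome-wide association analysis for extended
    pedigrees. Implements per-CpG linear mixed models with an additive
    polygenic random effect whose covariance is twice the pedigree kinship
    matrix, maximum-likelihood variance-component estimation via
    eigendecomposition rotation, likelihood-ratio tests of age association,
    Illumina 450K-style beta/M-value processing and probe QC, reference-based
    blood cell-type deconvolution, positional clustering of age-associated
    CpG sites into differentially methylated clusters (aDMCs), tests of
    group-dependent methylation aging rates (e.g. by metabolic-syndrome
    status), Fisher's-exact gene-set over-representation, and a synthetic
    cohort generator emulating multi-generation family structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
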