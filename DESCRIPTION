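Package: kirhla
Title: Maternal KIR and Fetal HLA-C Genotype Interaction Analysis of Birth Weight
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing maternal-fetal genotype (MFG) interactions
    between maternal killer immunoglobulin-like receptor (KIR) haplotypes and
    fetal HLA-C ligand groups on offspring birth weight. Provides a synthetic
    mother-offspring cohort generator with a configurable genotype
    imputation-error channel, conversion of imputed HLA/KIR output into
    analysis regressors (hard calls, C1/C2 ligand-group classification,
    parental-origin inference, posterior-probability dosages), pre-imputation
    SNP panel harmonization for Oxford HAPS/SAMPLE files, phenotype quality
    control with sample-size-derived outlier thresholds, six interaction
    linear mixed models with a mother-level random intercept, fixed-effect
    inverse-variance weighted meta-analysis, and a power study under varying
    imputation accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    withr
Config/testthat/edition: 3
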