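Package: rvscca
Title: Weighted RV Tests and Bootstrap-Enhanced Sparse CCA for Imaging Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate discovery, refinement and validation of association
    between SNP genotypes and longitudinal brain-atrophy endophenotypes under
    biased case-control sampling. Provides genotype quality control and
    linkage-region restriction, identity-by-state ancestry coordinates,
    per-region linear mixed models with random slopes for subject-specific
    rates of change, inverse probability weights from assumed population
    prevalences, weighted covariance-based RV coefficient permutation tests,
    sparse canonical correlation analysis by soft-thresholded rank-1
    approximation of the weighted cross-correlation matrix with bootstrap
    variable-importance probabilities, gene-level maxmean set statistics,
    and a seeded synthetic-cohort generator emulating the three-group
    longitudinal study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
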