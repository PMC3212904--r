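Package: cdgrs
Title: Case-Control Genetic Risk Scores for Crohn's Disease SNP Panels
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Complete case-control statistical pipeline for small SNP panels,
    modelled on the 22-variant Ashkenazi Jewish Crohn's disease panel:
    genotype quality control (Hardy-Weinberg equilibrium chi-square tests,
    pairwise linkage disequilibrium D'/r-squared via EM haplotype-frequency
    estimation from unphased genotypes), univariate allelic, carriage and
    compound-heterozygote odds ratios with Wald intervals, multivariate
    logistic regression by iteratively reweighted least squares, allele-count
    and effect-size-weighted genetic risk scores, threshold classification
    metrics (sensitivity, specificity, PPV, NPV, accuracy), ROC curves and
    AUC, analytic and simulation power for the allelic test, and a
    retrospectively ascertained synthetic-cohort simulator so that every
    stage is testable without access to the original genotypes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
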