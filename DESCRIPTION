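Package: endomr
Title: Two-Sample Mendelian Randomization for Disease Endophenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hybrid two-sample Mendelian randomization for quantitative
    disease endophenotypes: external SNP-exposure summary statistics are
    combined with in-sample covariate-adjusted SNP-outcome regressions via
    inverse-variance weighted, maximum-likelihood, weighted-median,
    weighted-mode and MR-Egger estimators, together with a sensitivity
    suite (Cochran Q heterogeneity, Egger intercept, MR-PRESSO resampling
    outlier detection, leave-one-SNP-out), allele harmonization of
    summary-statistic panels against cohort genotypes, APOE and polygenic
    risk score stratification, within-family false discovery rate
    correction, and a synthetic-cohort generator for validating the whole
    pipeline against known causal effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
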