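Package: hccnet
Title: Differential Connectivity and Somatic Copy Number Analysis for
    Paired Tumor and Adjacent-Normal Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of matched tumor (TU) and adjacent-normal
    (AN) tissue cohorts: gene-gene differential-correlation meta-analysis via
    the Fisher-Z heterogeneity Q statistic with label-permutation false
    discovery rates; smoothed somatic copy-number (sCNV) marker construction
    from SNP logR ratios with cis/trans association and trans-hotspot
    detection; per-gene forward stepwise variance decomposition onto sCNV
    markers; single-covariate Cox proportional-hazards survival screening
    with permutation-derived FDR thresholds; Fisher-exact set enrichment with
    per-marker observed/expected adjustment; and weighted coexpression module
    construction with scale-free soft-threshold selection. Includes a
    synthetic paired-cohort generator with ground-truth tables for recovery
    and calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
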