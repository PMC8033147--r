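Package: methtraj
Title: Longitudinal Modelling of DNA Methylation Trajectories in Childhood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Epigenome-wide longitudinal analysis of DNA methylation beta
    values from birth to late adolescence. Fits per-CpG Gaussian linear
    mixed models by maximum likelihood with a child-level random intercept,
    uncorrelated child-level random slopes and a crossed sample-plate
    random intercept; extends the linear model with piecewise slope changes
    at ages 6 and 9 years and with sex-by-age interactions; tests random
    slope variances by likelihood-ratio refits; classifies qualitative
    trajectories per age segment; quantifies cross-cohort stability
    (Spearman, intra-class correlation, per-cohort change estimates); and
    tests enrichment of trajectory classes in CpG annotation categories and
    published EWAS hit lists. A two-cohort synthetic data generator
    emulating a birth-cohort sampling design with partial longitudinal
    overlap makes the entire pipeline testable without restricted cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    data.table,
    yaml
Suggests:
    lme4,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
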