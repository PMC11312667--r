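Package: survscan
Title: Survival-Genetics Association Scanning with Martingale Residuals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Survival genetics of lifespan in large cohorts: Cox
    proportional-hazards fitting with Breslow baseline hazard and
    Martingale residuals used as a quantitative phenotype for
    genome-wide association scans; quality control of common variants
    (missingness, minor allele frequency, exact Hardy-Weinberg test);
    rare-variant classification into loss-of-function and
    predicted-damaging missense classes, carrier collapsing, burden,
    SKAT and SKAT-O gene-based tests with Davies/Liu quadratic-form
    p-values; per-variant carrier Cox regressions; Bayesian
    colocalization of paired association signals via approximate Bayes
    factors; variant-allele-fraction summaries with bootstrap
    confidence intervals for clonal-hematopoiesis flagging;
    phenome-wide association scans of carrier status; and a synthetic
    cohort generator with Weibull-baseline proportional-hazards
    survival and administrative censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
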