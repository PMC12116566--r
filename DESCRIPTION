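Package: pvsignal
Title: Pharmacovigilance Signal Detection for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for disproportionality analysis of
    spontaneous adverse-event reports in the FDA Adverse Event Reporting
    System (FAERS) quarterly ASCII dialect. Reads the five core tables
    (DEMO, DRUG, REAC, THER, OUTC), applies the FDA-recommended
    case-level deduplication, extracts drug cohorts by generic and brand
    name with a MedDRA-like preferred-term to system-organ-class stub,
    and computes four signal-detection statistics per drug-event pair:
    the reporting odds ratio (ROR), proportional reporting ratio (PRR)
    with Pearson chi-squared, the Bayesian confidence propagation neural
    network information component (IC), and the multi-item gamma-Poisson
    shrinker empirical Bayes geometric mean (EBGM). Also provides Weibull
    time-to-onset modelling, multivariate logistic risk-factor
    regression, and a synthetic FAERS-like report generator with planted
    associations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
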