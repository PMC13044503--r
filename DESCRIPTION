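Package: natmets
Title: Natural-History Modelling of Metastasis-Free Survival in ER+ Breast
    Cancer Under Time-Varying Hormonal Treatment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a biologically motivated natural-history model of
    oestrogen receptor-positive breast cancer that links exponential primary
    tumour growth with a gamma-distributed inverse growth rate, a
    non-homogeneous Poisson process of viable metastatic seeding, mammography
    screening with size-dependent sensitivity, and a piecewise (multi-period)
    hormonal-treatment effect on metastatic growth. Provides the induced cure
    model for time from primary diagnosis to detection of distant metastases,
    per-patient likelihood contributions for screen-detected and symptomatic
    cases with screening-history back-calculation, maximum-likelihood fitting
    with nonparametric bootstrap confidence intervals, a validated synthetic
    cohort simulator, model-based prediction of metastasis-free survival under
    alternative treatment durations, and extended Kaplan-Meier goodness-of-fit
    tools for cohorts with treatment switching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
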