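Package: thyrobmd
Title: Benchmark-Dose Analysis of Blood Nickel and Thyroid Homeostasis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline linking blood nickel concentration to
    thyroid function in biomonitoring cohorts. Computes the thyroid
    homeostasis parameters SPINA-GT (secretory capacity) and SPINA-GD
    (deiodinase activity) from serum TSH, fT4 and fT3; converts hormones
    and derived parameters to quantal (in/out of reference range)
    outcomes; provides stratified descriptive statistics and Spearman
    correlations with Fisher-z confidence intervals; and estimates
    model-averaged benchmark doses (BMD) for quantal endpoints with
    bootstrap BMDL/BMDU confidence limits across a classical suite of
    dose-response models (logistic, probit, log-logistic, log-probit,
    Weibull, gamma, two-stage). Includes a seeded synthetic-cohort
    generator so every stage is testable without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
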