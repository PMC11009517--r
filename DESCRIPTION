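Package: diigrs
Title: Dietary Inflammatory Index, FTO Genetic Risk Scores and Gene-Diet
    Interaction Analysis for Prospective Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable implementation of the analysis chain used in
    gene-diet interaction cohort studies of obesity: Dietary Inflammatory
    Index (DII) scoring from nutrient-intake tables, odds-ratio-weighted
    genetic risk scores over FTO variants, derived adiposity measures (BMI,
    waist ratios, Visceral Adiposity Index) and their longitudinal changes,
    an auditable participant-exclusion cascade, and stratified
    quartile-by-genotype logistic models with trend and interaction tests.
    A synthetic cohort generator reproduces the statistical structure the
    analysis assumes, so the whole pipeline is testable without access to
    individual-level cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
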