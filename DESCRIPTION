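Package: perisleep
Title: Claims-Based Phenotyping of Maternal Sleep Disorders and Perinatal Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing pregnancy episodes from ICD-coded
    administrative claims, building an eligible maternal cohort with
    mother-infant dyad linkage, phenotyping sleep-disorder exposure and
    maternal and birth outcomes, and estimating period prevalence and
    adjusted odds ratios with binary and multinomial logistic regression.
    Includes a synthetic claims generator with planted effect sizes and
    full ground truth so every pipeline stage can be validated without
    access to proprietary claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nnet,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
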