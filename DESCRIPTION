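Package: pmcindex
Title: Policy Modeling Consistency (PMC) Index Evaluation of Policy Texts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative evaluation of policy-text corpora with the Policy
    Modeling Consistency (PMC) index: binary coding of second-level indicators
    against a hierarchical indicator schema, exact-thirds dimension scoring,
    index grading and ranking, PMC surface and radar exports, scenario-based
    sensitivity analysis of indicator coverage, and within-dimension Pearson
    chi-square consistency checks. Includes a text-mining front end (term
    frequencies, co-occurrence networks), synthetic-data generators with known
    ground truth, and a bundled evaluation dataset of 22 Chinese national
    medical-quality intelligent-management policies (2016-2025).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
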