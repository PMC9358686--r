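Package: herbminer
Title: Prescription Pattern Mining for Herbal Analgesic Screening in
    Rheumatoid Arthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining traditional Chinese medicine prescription
    records from rheumatoid-arthritis chronic-pain cases: dictionary-driven
    terminology standardization, clinical eligibility screening, symptom and
    herb frequency analysis with a high-frequency enrollment filter,
    level-wise Apriori association-rule mining of second- and third-order
    herb and herb-symptom rules under support/confidence/lift thresholds,
    monograph annotation and attribute network export, and agglomerative
    hierarchical clustering of co-prescribed herbs. Includes a latent-class
    synthetic prescription generator with closed-form expected rule metrics
    for validation, and an end-to-end pipeline producing a reproducible
    report bundle.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    ape,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
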