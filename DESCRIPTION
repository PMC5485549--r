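Package: icd9phenotype
Title: ICD-9-CM Claims Phenotyping for Decompressive Craniectomy for Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule engine for phenotyping hospital administrative claims by
    ICD-9-CM diagnosis and procedure codes, with wildcard code-family
    patterns, exclusion precedence, and explainable match traces.  Ships a
    validated rule set identifying decompressive craniectomy for
    space-occupying supratentorial infarction, secondary indicators for
    excision of infarcted tissue and hemorrhagic conversion, diagnostic
    accuracy metrics (sensitivity, specificity, predictive values) with
    exact binomial confidence intervals, a deterministic reconstruction of
    the validation cohort, a seeded synthetic claims generator, and a
    command-line interface over delimited-text claims files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
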