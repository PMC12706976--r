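Package: acmgrules
Title: Automated ACMG/AMP Germline Variant Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule engine for germline variant interpretation under the
    ACMG/AMP 2015 framework. Evaluates 19 of the 28 evidence codes
    automatically from annotated variants, with dynamic strength weighting
    on a five-level ladder (supporting to stand-alone), gene-constraint
    (LOEUF) stratified population-frequency cutoffs, ClinVar review-status
    weighting, calibrated in-silico predictor ladders, and a modified
    combining procedure with ordered two-pass conflict checks. Includes
    deterministic reference-bundle builders that reproduce the published
    preprocessing filters from generic local tables, an external call file
    mechanism for manual codes and overrides, a synthetic fixture
    generator, and benchmark concordance metrics (per-category and
    per-code sensitivity, specificity, precision and F1).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    vcfR
Config/testthat/edition: 3
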