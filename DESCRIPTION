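Package: pgscreen
Title: Polygenic Score Construction, Risk Stratification and Screening-Rule
    Evaluation for Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates family-based case-control cohorts for type 2 diabetes
    under a liability-threshold model with full generative ground truth,
    builds clumping-and-thresholding polygenic scores from a single-cohort
    association scan, and evaluates them the way screening studies do:
    percentile-bin risk stratification with odds ratios against the total
    population, USPSTF- and ADA-style screening rules with and without a
    polygenic-score criterion, and nested logistic model comparisons of
    family history versus genetic risk with Cox-Snell pseudo R-squared and
    held-out AUC. Cohorts and score weights round-trip through delimited
    text and PGS Catalog scoring-file formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
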