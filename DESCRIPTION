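Package: namecohort
Title: Surname-List Cohort Identification and Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Build, screen and manage ethnicity-specific surname lists;
    assign every member of a population roster to an ethnic group by exact
    surname matching; resolve multi-response self-reported ethnicity from
    cross-sectional survey questions into a gold standard; and compute
    survey-weighted diagnostic test characteristics (sensitivity,
    specificity, positive and negative predictive value), overall and
    stratified, with percentile-bootstrap confidence intervals. Includes a
    synthetic roster and survey generator with a closed-form oracle for the
    expected test characteristics, and packaged starter lists of the 200
    most common South Asian, Chinese and general-population surnames in
    Ontario.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    stringi
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
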