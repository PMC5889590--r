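Package: cmgap
Title: Continuous Medication Gap Adherence from Pharmacy Claims with
    Self-Report Convergent Validity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures secondary medication adherence from pharmacy
    dispensing claims with the continuous medication gap (CMG), using a
    time-forward supply-carryover algorithm in which stockpiled pills
    carry into future refill intervals but never erase gaps already
    incurred. Classifies adherence at the 20% gap threshold, selects and
    categorizes 7-day recall self-reports of missed pill days from
    automated telephone queries and structured interviews, and evaluates
    their convergent validity against CMG with exact
    (Fisher-Freeman-Halton) tests and cross-mode concordance summaries.
    Includes a synthetic claims cohort generator with known ground-truth
    adherence for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
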