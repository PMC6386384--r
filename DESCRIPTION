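Package: stiecon
Title: Whole-System Cost-Effectiveness Analysis of Online STI Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the cost-effectiveness of online (postal
    self-sampling) testing for sexually transmitted infections at the level of
    a whole local sexual health economy. Takes individual-level attendance
    records coded with GUMCAD (Genito-Urinary Medicine Clinical Activity
    Dataset) service codes through exclusion filtering, same-day record
    collapse and a six-week one-test-per-person deduplication, then computes
    per-quarter testing volumes, diagnoses and composite positivity by
    setting, assigns London sexual-health tariffs to classified visits to
    produce period cost summaries (cost per test, cost per diagnosis), and
    provides closed-form scenario models for blended cost per test, cost per
    diagnosis as a function of the online/clinic positivity ratio (with its
    break-even rule), the kit return-rate cost curve, and cross-area cost per
    diagnosis comparisons. A seeded synthetic cohort generator emulates the
    statistical structure of clinic and online attendance streams so the full
    pipeline is testable without access to confidential patient records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    tibble,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
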