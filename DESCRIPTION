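Package: codesifter
Title: Build, Review and Apply Clinical Code Lists for Primary Care Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing clinical code lists for electronic health
    record phenotyping. Searches clinical-code and product dictionaries with
    word-stub and code-prefix matching rules, exports review templates for
    expert panels, manages tiered (QOF / conservative / speculative) code
    lists with enforced superset relations, flags cases in patient event
    tables, and computes prevalence and incidence by UK financial year to
    compare case definitions. Includes a synthetic-data generator with known
    ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    readr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
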