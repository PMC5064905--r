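Package: etiqh
Title: Weighted-Checklist Quality-of-Care Scoring for Health Facility Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engine for the e-TIQH (electronic Tool to Improve Quality of
    Healthcare) assessment methodology used in supportive supervision of
    primary healthcare facilities. Models a six-dimension instrument of
    weighted yes/no/not-applicable verification criteria, implements the
    two-step weighted score calculation with NA-aware denominators,
    aggregates scores across facilities, councils, regions and ownership
    categories, tests longitudinal trends with paired t-tests over complete
    facility pairs, and generates synthetic multi-round assessment data with
    controllable quality levels for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    tibble,
    dplyr,
    tidyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
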