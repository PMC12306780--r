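Package: crmslife
Title: Fertility Charting, Intentions, and Life-Table Effectiveness Analysis
    for the Creighton Model FertilityCare System
Version: 0.1.0
Authors@R: person("CrMS", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing prospective cohort data collected during use
    of the Creighton Model FertilityCare System (CrMS): day-level fertility
    classification of standardized mucus/bleeding charts, peak-day
    identification, reconciliation of couple pregnancy intentions from
    start-of-cycle questionnaires, intention-by-behavior cross-tabulation,
    correct-use cycle cascades, single-decrement cycle-based and
    multiple-decrement ordinal-month life tables of pregnancy probability,
    and a rule-based CrMS pregnancy classifier.  Includes a seeded synthetic
    cohort generator with known ground truth for validating every pipeline
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
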