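Package: cycleguard
Title: Rule-Based Decision Support for Chemotherapy-Cycle Prescription
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Knowledge-based clinical decision support for pre-cycle
    evaluation of chemotherapy prescriptions. Grades electronic
    patient-reported outcome (ePRO) symptom questionnaires on the
    NCI-CTCAE 0-4 scale, screens laboratory panels (blood counts, liver
    and kidney function) against configurable reference ranges, and
    combines both with data-freshness rules into a three-tier
    go/evaluate/postpone recommendation with a machine-readable audit
    trail. Includes a scheduling state machine that times questionnaire
    and laboratory collection around each planned infusion and
    re-programs both when a cycle is postponed, a synthetic-cohort
    simulator, and tabular performance and symptom-prevalence reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
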