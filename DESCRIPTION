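Package: medsig
Title: Medication Sig Parsing and Decision-Support Preprocessing for EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning messy electronic-health-record medication and
    diagnosis data into clinical decision-support inputs. Parses free-text
    drug-name and sig (prescription instruction) fields in the VistA dialect to
    extract dose, unit and schedule and compute total daily dose; normalizes
    decorated drug names and classifies them against a formulary into supplies,
    excluded classes and drugs of interest for polypharmacy screening; builds
    recruitment stratification grids (age band by drug-of-interest count, with
    hypertension/diabetes flags from ICD-9 codes); emulates a staging store that
    reduces histories to disease flags and prior-medication last-prescription
    dates; implements a dependent-field lab panel with automatic FIB-4
    derivation and manual override; and generates seeded ground-truthed
    synthetic fixtures so every component is testable without real patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
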