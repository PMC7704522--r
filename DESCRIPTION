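Package: baroN1
Title: Individual Baroreflex-Chemoreflex Interaction Testing from Repeated
    Phenylephrine Boli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies individual (N-of-1) baroreflex-chemoreflex interaction
    from repeated phenylephrine bolus responses recorded beat-to-beat. Extracts
    per-bolus cardiovagal baroreflex sensitivity (Oxford pharmacological
    technique: regression of RR interval on systolic pressure during the
    drug-induced pressure rise) and pressor sensitivity (systolic pressure rise
    per standard bolus), tests per-subject condition differences with unpaired
    t statistics, aggregates to cohort level with paired tests, plans the
    number of bolus repetitions by Monte-Carlo sensitivity analysis, and
    computes hypoxic respiratory chemoreflex responses. Includes a calibrated
    beat-to-beat hemodynamic simulator so the full pipeline is testable
    without physiological recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    ggplot2,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
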