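Package: vaxtiming
Title: Immunization Coverage, Timeliness and Sequencing Audits from Vaccination-Card Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies child vaccination-card records against a configurable
    Expanded Programme on Immunization (EPI) schedule: full-immunization status
    (FIC) by 12 months, per-dose timeliness (early, timely, delayed, missing),
    and out-of-sequence administration (late BCG, pentavalent/polio doses split
    across days, pentavalent with or after measles). Summarizes cohorts with
    coverage tables, Kaplan-Meier age-at-vaccination curves, log-rank tests,
    Mood's median tests and chi-square tests of independence, all implemented
    from first principles. Includes a calibrated synthetic cohort generator
    that emulates longitudinal demographic-surveillance card data so the whole
    pipeline is testable without access to restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
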