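Package: aspirinpd
Title: Pharmacokinetic-Pharmacodynamic Simulation of Low-Dose Aspirin and
    Platelet COX-1 Inhibition in Myeloproliferative Neoplasms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multiscale simulation of the action of low-dose aspirin on
    platelet cyclooxygenase-1 (COX-1) and serum thromboxane B2 (TXB2)
    production, with subgroup calibration for polycythemia vera (PV).
    Couples a linear three-compartment aspirin pharmacokinetic model with
    an age-structured megakaryocyte/platelet COX-1 turnover model under
    saturable irreversible acetylation, aggregates birth cohorts into a
    whole-body COX-1 capacity mapped to serum TXB2 as percent of the
    pre-aspirin basal level, and provides dosing-regimen experiments
    (once vs. twice daily, missed dose), one-dimensional calibration of
    the COX-1 biosynthesis fold, and a seeded virtual-cohort generator
    with the study cohort's marginal and rank-correlation structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
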