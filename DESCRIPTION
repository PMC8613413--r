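Package: stimpipe
Title: Individualized rTMS Targeting, Dosing, and Working-Memory Experiment
    Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of an individualized repetitive
    transcranial magnetic stimulation (rTMS) targeting-and-dosing pipeline for
    working-memory experiments. Provides modal controllability on structural
    connectomes, block-design GLM activation mapping with a double-gamma HRF,
    the activation-gate plus maximal-controllability target selection rule,
    scalp projection and sulcal-normal coil orientation, electric-field dose
    calibration to a reference E100 exposure, a 2-down-1-up adaptive staircase
    with sigmoid difficulty fitting, a factorial within-subject experiment
    scheduler, and the associated repeated-measures behavioral analyses. A
    seeded synthetic-cohort generator makes the whole pipeline runnable
    end-to-end without neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    withr,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
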