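Package: la4dflow
Title: Left Atrial 4D-Flow CMR Hemodynamics and Function Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies left atrial (LA) hemodynamics from time-resolved
    three-directional phase-contrast (4D flow) velocity fields: residual
    velocity-offset correction from stationary tissue, velocity-time curves,
    windowed mean/peak velocities, blood stasis fraction, and voxelwise
    kinetic energy (absolute and indexed to maximum LA volume). Also derives
    LA volume curves with reservoir/conduit/booster function decomposition,
    biplane area-length left ventricular volumes, feature-tracking global
    longitudinal strain phases from tracked contours, and the group-level
    statistical layer (t / Mann-Whitney / Fisher / paired-t tests, Spearman
    correlation, intraclass correlation, CHA2DS2-VASc scoring). Includes a
    synthetic dynamic-atrium phantom generator with analytic ground truth
    for validation, with presets emulating paroxysmal atrial fibrillation
    and control cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
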