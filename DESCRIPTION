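Package: sfeptr
Title: Single-Cell Lipid Screening Pipeline for SFE-PTR Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Data-processing pipeline for supercritical-fluid-extraction
    proton-transfer-reaction mass spectrometry (SFE-PTR MS) screening of
    lipophilic metabolites from single cells. Provides a synthetic run
    generator with known ground truth (Poisson ion counting, bell-shaped
    elution profiles, decaying reagent background, lock-mass references,
    polynomial mass-axis distortion), third-order-polynomial TOF mass
    calibration with lock-mass correction, spectrum co-addition and
    extracted-ion-profile construction, sample/background/blank-matched ion
    classification, formula annotation of PTR ion species (protonation,
    electron transfer, hydroxide transfer) against an SDF structure
    database with isomer counting, and Poisson-statistics quantitation
    with a 100-count limit of quantitation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ChemmineR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
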