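Package: fieldsar
Title: Receptor-Guided 3D-QSAR and Interaction Analysis for Docked
    Ligand Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-docking structure-activity analysis for congeneric
    ligand series sharing a receptor frame: common-graph (maximum common
    substructure) pose RMSD metrics, essential-interaction pose filtering,
    per-residue protein-ligand interaction fingerprints with occurrence
    profiles, and a receptor-guided CoMFA-style 3D-QSAR built from steric
    and electrostatic probe fields (grid construction, pretreatment,
    block-unscaled weighting, smart region definition, NIPALS partial
    least squares with leave-one-out cross-validation, external test
    statistics and coefficient contour export). Includes a synthetic
    congeneric-series generator with planted field effects so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
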