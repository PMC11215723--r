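Package: stdepitope
Title: Reduced Relaxation-Matrix Prediction of STD NMR Initial Slopes and
    Epitope-Based Scoring of Protein-Ligand Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast prediction of saturation transfer difference (STD) NMR
    initial slopes (STD0) from 3D models of low-affinity protein-ligand
    complexes using a reduced dipolar cross-relaxation matrix, and scoring
    of static structures, docking-pose ensembles and molecular-dynamics
    trajectories against experimental binding epitopes via the NOE
    R-factor. Includes a full two-site-exchange relaxation/exchange
    build-up solver used as an internal validation oracle on small spin
    systems, mono-exponential build-up curve fitting for experimental
    STD0 extraction, readers for PDB structures and AMBER-dialect ASCII
    topologies/trajectories, and deterministic synthetic fixture
    generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
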