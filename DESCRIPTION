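Package: bosscore
Title: Patient-Specific Femoral Bone Strength (BOS) Scores from Calibrated CT
Version: 0.1.0
Authors@R:
    person("Orthopaedic", "Modelling", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes patient-specific Bone Strength (BOS) scores for femurs
    with osteolytic metastases from calibrated computed-tomography volumes.
    The pipeline covers quantitative-CT phantom calibration (Hounsfield units
    to calcium-equivalent density), classical femur segmentation, stance
    alignment and proximal cropping, voxel-to-tetrahedron meshing with
    density-based elastoplastic material mapping, a displacement-controlled
    nonlinear finite-element simulation loaded to the peak total reaction
    force, fracture-risk classification against fixed score thresholds, a
    clinical report rendered against a score database, and decision-impact
    auditing of a pilot cohort. A synthetic-CT generator with known ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
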