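Package: fcdyn
Title: Glycoform Dynamics Descriptors for IgG1 Fc Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory descriptor analysis for IgG1 Fc glycoform simulations:
    glycan-protein minimum-distance and contact dynamics with detachment-event
    detection, C'E loop conformational-ensemble quantification and three-state
    classification, Fc receptor-interface geometry (D_AB), Cgamma2-Cgamma3
    orientation angles, radius of gyration, and first/second-half convergence
    checks. Includes exact geometric primitives (Kabsch superposition,
    selection-based RMSD), PDB/DCD trajectory input, and a synthetic-trajectory
    generator with planted ground truth for validating every descriptor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
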