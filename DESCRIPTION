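Package: channelgeom
Title: Quantitative Structural Comparison of Tetrameric Ion Channels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Geometry analyses for tetrameric ligand-gated ion channel
    structures, built around the kainate-receptor (GluK2/K5) architecture:
    largest-inscribed-sphere pore-radius profiling with constriction calling
    and residue attribution, subunit-pair symmetry RMSD by rigid-body
    superposition, ligand-binding-domain centre-of-mass geometry,
    inter-state angle decomposition (in-plane rotation, out-of-plane tilt,
    clamshell cleft closure), and per-residue lateral/vertical linker
    deviation profiles with divergence-residue detection.  Includes
    generators for idealized synthetic assemblies (helical bundles, pore
    lattices, clamshell domains, paired conformational states) with exact
    ground truth, so every estimator is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
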