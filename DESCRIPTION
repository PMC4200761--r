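Package: surfcomp
Title: Patch-Based Molecular Surface Complementarity for Ligand Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Represents protein binding pockets and small-molecule ligands as
    sets of segmented molecular-surface patches, each described by
    rotation-invariant 3D Zernike descriptors of surface shape and
    electrostatic potential.  Patches are matched across a pocket-ligand
    pair with an epsilon-scaling auction assignment under a three-term
    distance score, and ligand libraries are ranked by a pocket-ligand
    complementarity score.  Includes readers for PDB, PQR, MOL2, SDF and
    OpenDX scalar grids, a Gaussian-density molecular surface engine with a
    screened-Coulomb electrostatics model, conformer deduplication,
    evaluation utilities (native-contact match success rate, weight grid
    searches, enrichment factors, ROC AUC) and deterministic synthetic
    fixture generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
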