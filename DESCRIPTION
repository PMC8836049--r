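Package: mdunfold
Title: Early Unfolding Analysis of Two-Domain Beta-Sandwich Proteins from
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conformational analysis of early protein-unfolding trajectories,
    developed around the two-domain Greek-key beta-sandwich fold of human
    gammaD-crystallin. Reads multi-model PDB trajectories, computes native
    contact fractions, residue contact maps and subtractive maps, minimal
    DSSP-style secondary-structure assignment with ordered unfolding-event
    detection, aromatic-interaction persistence and cluster formation,
    essential-dynamics principal component analysis, interdomain
    closure/twist decomposition, and potential-energy bookkeeping with a
    pluggable scorer. Includes a synthetic-trajectory generator with scripted
    ground truth so every analysis stage is testable without running MD.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    bio3d,
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
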