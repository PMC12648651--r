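Package: confocus
Title: Conformer Ensemble Sampling and Collision Cross-Section Focusing
    for Ion-Mobility Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An autonomous pipeline for generating gas-phase conformer
    ensembles of singly protonated or deprotonated small-molecule ions
    observed in ion-mobility mass spectrometry (IM-MS). Enumerates
    titratable nitrogen and oxygen sites, builds and ranks [M+H]+ / [M-H]-
    charge models through a two-tier pluggable scorer, generates diverse
    low-energy conformers with a deterministic torsion-grid generator,
    focuses each ensemble around a user-supplied reference collision
    cross-section (CCS) using a projection-approximation CCS estimator,
    reduces conformational redundancy with a stepped normal-walk over the
    ensemble RMSD distribution, and scores candidate ensembles by
    Boltzmann-weighted CCS error against a 3 percent experimental
    viability criterion.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on
    the PATH, used for seeded 3-D embedding of SMILES input.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
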