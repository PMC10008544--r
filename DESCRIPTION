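Package: flexrin
Title: Confidence-Flexibility Concordance and Residue Interaction
    Networks for Conformer Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of multi-model protein structures (molecular dynamics
    snapshots or populations of predicted models) carrying per-residue
    confidence (pLDDT) in the B-factor column.  Computes per-residue
    root-mean-square fluctuation (RMSF) and RMSD series from conformer
    ensembles, the reverse min-max normalised confidence score and its
    Pearson concordance with observed flexibility, heavy-atom residue
    interaction networks with cofactor and substrate ligand groups as
    vertices, per-frame ligand contact frequencies, rigid-body
    (Kabsch) cofactor transfer from a holo template into an apo model,
    and neighbor-joining trees from pairwise structural RMSD matrices.
    Includes a deterministic synthetic-ensemble generator with known
    ground-truth fluctuation profiles and ligand contact schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    igraph,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
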