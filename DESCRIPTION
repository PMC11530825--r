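Package: rnadyn
Title: Dynamic Contact, Energy, and Geometry Analysis of Nucleic-Acid
    Structural Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for structural ensembles of antisense
    oligonucleotide (ASO) RNA-hairpin complexes: residue-pair contact
    dynamics with specific/nonspecific classification and occupancy
    filtering, four-group short-range Coulomb/Lennard-Jones interaction
    energy decomposition, ensemble descriptors (RMSD, per-residue RMSF,
    radius of gyration, PCA), nucleic-acid geometry (backbone torsions,
    sugar pucker pseudorotation, base-pair and step helical parameters),
    and base-pair/Hoogsteen-edge and triple-base-pair detection. Includes
    a seeded synthetic-ensemble generator with known ground truth so every
    stage of the workflow is testable without external trajectory data.
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
    withr
Config/testthat/edition: 3
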