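Package: g4loops
Title: Conformational Survey of G-Quadruplex TTA/UUA Propeller Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying the conformations of TTA (DNA) and UUA (RNA)
    propeller loops in parallel human telomeric G-quadruplex structures.
    Reads PDB/mmCIF coordinate files, computes backbone and glycosidic
    torsion angles, Altona-Sundaralingam sugar pseudorotation parameters and
    pucker classes, classifies loops into twelve base-stacking types,
    superposes G-quartet cores with cyclic-symmetry handling (Kabsch), and
    aggregates per-loop results into census and consensus tables. Includes a
    synthetic-structure generator for fully offline testing of every
    geometric primitive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
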