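Package: bmcshell
Title: Geometry and Interface Analysis of Bacterial Microcompartment Shells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs Caspar-Klug icosahedral and prolate (Q-number)
    shell lattices from (h, k) and (h', k') indices, predicts hexamer and
    pentamer stoichiometry, and classifies capsomere-capsomere interfaces
    into symmetry orbits.  Measures shell geometry on atomic or
    pseudo-atomic models: capsomere plane fitting, inter-capsomere bend
    (alpha) and twist (beta) angles, cyclic-symmetry-aware superposition
    RMSD, and shell diameter by the averaged-diagonal procedure used for
    electron micrographs.  Computes residue-level interface chemistry
    (hydrogen bonds, salt bridges, Shrake-Rupley solvent-accessible and
    buried surface areas) and scans scaffold-protein linker sequences for
    [IV][TS]G anchor motifs.  A synthetic-shell and synthetic-linker
    generator with ground-truth manifests makes every stage testable
    without deposited structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
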