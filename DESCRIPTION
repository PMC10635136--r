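Package: capsidlattice
Title: Caspar-Klug Icosahedral Capsid Lattices and Capsomer Symmetry Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs Caspar-Klug icosahedral capsid lattices from hexagonal
    lattice steps (h,k), classifies every capsomer against the 31 global
    icosahedral symmetry axes, and verifies by two independent routes (exact
    lattice arithmetic and 3D geometric brute force) that a capsid contains a
    hexamer centered on a true 3-fold axis if and only if its triangulation
    number is a multiple of three. Includes protein stoichiometry and genome
    packing density accounting for tailed bacteriophage capsids, a T-number
    survey reproducing the split/skew-hexamer compatibility classification,
    and writers for CSV, JSON, pseudo-atom PDB and OBJ mesh output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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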