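Package: resclique
Type: Package
Title: Higher-Order Residue Interactions in Protein Structures
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enumerates higher-order residue interactions in protein
    structures: pairwise, triplet and quadruplet interactions defined as
    2-, 3- and 4-cliques of the residue contact graph built from
    C-alpha/C-beta distance geometry within a user-defined distance
    window. Supports whole-structure enumeration, anchored-residue and
    residue-type queries on single- and multi-chain structures read from
    PDB files, tab-delimited reporting, RasMol/Jmol selection scripts,
    and synthetic-structure generators (ideal helices, regular polyhedra,
    random packings) with a brute-force clique oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
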