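Package: taz3d
Title: Structure-Based Functional Annotation of Tafazzin Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Structural analysis toolkit for the mitochondrial transacylase
    tafazzin and its Barth-syndrome missense variants. Computes Shrake-Rupley
    solvent accessibility and buried structural cores, performs global pairwise
    alignment with template-accessibility-weighted gap penalties, detects
    substrate-binding clefts on a protein-solvent-protein grid and tabulates
    their residues by exon, finds exposed basic surface patches and
    hydropathy-based transmembrane or disorder segments, analyses the phosphate
    geometry of cardiolipin-like dimeric phospholipids, and classifies missense
    mutations into structural location classes with electrostatic and stability
    flags and proposed functional effects. Includes deterministic synthetic
    generators (helices, cavity/cup/tube constructs, cardiolipin-like ligands)
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
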