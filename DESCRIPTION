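Package: sigpep
Title: Phylogenetic and Functional Classification of Short Genomic
    Fragments with Signature Peptides
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds databases of amino-acid k-mers (signature peptides,
    default k = 10) shared by at least two reference proteomes, places each
    signature on a rooted reference phylogeny at the least common ancestor
    of the genomes containing it, and classifies DNA reads by six-frame
    translation, exact peptide matching and a greatest-common-descendant
    rule. Samples are summarised as phylogenetic profiles over tree nodes
    and fractional functional profiles over subsystems, with normalized
    dot-product similarity, hierarchical roll-ups and per-node differential
    tests. Also provides maximal exact-match enumeration between proteomes,
    run-length histograms with exponential-falloff fits, analytic
    random-match expectations, and synthetic fixture generators (planted
    signature peptides, error-free fixed-length shotgun reads, per-base
    mutation) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
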