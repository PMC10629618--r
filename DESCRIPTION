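Package: protfam
Title: Protein Sequence Matching, Masking, Clustering and Gene-Fusion
    Detection for Genome Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale genome-comparison toolkit for protein sequence
    collections: MD5 fingerprinting for exact sequence matching and
    identifier cross-mapping between databases; sensitive detection and
    selective masking of compositionally biased (low-complexity) tracts
    by Smith-Waterman comparison against residue homopolymers with
    infinite gap penalties; deterministic re-encoding of genome FASTA
    collections into structured CoGenT-style identifiers; a local
    alignment search driver; native Markov clustering (MCL) of sequence
    similarity graphs into protein families; binary hit-matrix
    symmetrification with multi-domain protein detection; and detection
    of gene-fusion events (composite proteins matching two or more
    mutually unrelated components at distinct regions). The stages
    compose into a reproducible genome-comparison workflow driven by
    seeded synthetic fixtures or real BLAST tabular pairs-lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    igraph,
    digest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
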