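Package: ltrclone
Title: LTR Retrotransposon Insertion Polymorphism and Clonality Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genotypes LTR retrotransposon insertions in short-read data from
    single individuals using 100 bp insertion-boundary tags ("LTR-tags"), and
    tests clonal versus sexual inheritance of the resulting presence/absence
    matrices. Candidate full-length elements are filtered for gene overlap,
    assembly gaps and repeat-homology support; boundary tags are extracted,
    collapsed by sequence divergence, and scored against reads with a
    best-read local-alignment score. Clonality is assessed with the parsimony
    consistency index, character compatibility, and the standardized index of
    association with a permutation null, and the frequency of sex is estimated
    by rejection approximate Bayesian computation against a forward-time
    facultative-sex Wright-Fisher simulator. A synthetic-data module plants
    elements in simulated genomes and generates error-bearing reads with known
    ground truth, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    ape,
    phangorn,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
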