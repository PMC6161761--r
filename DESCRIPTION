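Package: cnepairs
Title: Evolutionary and Epigenetic Analysis of Adjacent Conserved Noncoding Element Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds pairs of adjacent conserved noncoding elements (CNEs) from
    conserved-element interval sets, identifies their orthologs across a mammalian
    phylogeny by reciprocal best hits, reconstructs ancestral inter-CNE distances
    and transposon content under a Brownian-motion model, and computes genome
    size-normalized distance and transposon difference statistics (nRDD, nRTD).
    Includes randomization tests for transposon-density depletion, extraction of
    histone-modification enrichment profiles around CNE pairs, clustering of pairs
    with a Kohonen self-organizing map, and odds-ratio enrichment of pair groups
    in map units with FDR control. A synthetic-data generator with planted ground
    truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    mclust,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
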