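Package: rapphr
Title: Genome Mining and Evolutionary Analysis of Rap-Phr Quorum-Sensing Cassettes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining Bacillus-type rap-phr quorum-sensing cassettes from
    genome assemblies and analysing their evolution. Receptor homologs are located by
    translated homology search, downstream propeptide open reading frames are detected
    with a position-weight-matrix secretion-signal score, putative penta/hexapeptide
    autoinducers are called from conservation patterns, and intragenic autoinducer
    repeats and phr gene duplications are detected. Receptor trees are clustered into
    maximal monophyletic same-peptide groups; cassettes are classified as core or
    horizontally transferred from GC content; presence/absence matrices, per-species
    frequencies and rarefaction curves summarise population structure; and gain/loss of
    downstream-target regulation is reconstructed by equal-cost Sankoff parsimony. A
    synthetic-genome generator with full ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vegan,
    graphics,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    pROC,
    jsonlite,
    optparse,
    readxl
Config/testthat/edition: 3
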