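Package: ismilp
Title: Genome-Wide Intron-Spanning and Intron-Length Polymorphism Marker Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs intron-spanning PCR markers (ISM) from the exonic sequences
    flanking the introns of annotated genes, converts them to intron-length
    polymorphism (ILP) markers by locating each intron in a second genome,
    aligning with affine gap penalties and calling left-normalized
    insertions/deletions, and predicts fragment-length polymorphism by
    in-silico PCR. Also computes the downstream marker analytics used in rice
    genetic studies: marker census and density tables, fragment-length
    polymorphism distributions, amplification/polymorphism summaries, linkage
    map saturation, polymorphism information content, Nei-Li band-sharing
    distances, neighbor-joining trees with marker bootstrap, chi-square
    segregation screens and comparative-Ct expression ratios. A simulator
    generates reference/query genome pairs with planted intronic variants and
    group-structured genotype panels so every pipeline stage can be validated
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    ape,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
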