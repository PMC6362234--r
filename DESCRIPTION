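Package: caltscan
Title: Comparative Genomics of CcoA-Like Copper Transporter Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for the comparative-genomics
    characterisation of CcoA-like transporter (CalT) protein families:
    protein sequence similarity networks with alignment-score thresholded
    edges, transmembrane-helix prediction and Cu-binding motif screening
    (MxxxM/HxxxM in TM7/TM8), center-star multiple alignment with
    column-quality filtering and sequence logos, neighbor-joining
    phylogenies with bootstrap supports, and gene-neighborhood
    conservation analysis at the genus, family and order ranks.  Includes
    a seeded synthetic-pangenome generator with planted ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    ape,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
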