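Package: quartetconv
Title: Quartet-Based Detection of Gene Conversion Between
    Polyploidy-Derived Duplicate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects whole-gene and partial-gene conversion between
    duplicate genes retained from a whole-genome duplication, using
    homologous gene quartets built from intra- and inter-genome
    collinear blocks. Implements Nei-Gojobori (1986) Ka/Ks with
    Jukes-Cantor correction, gap-constrained synteny block chaining,
    kernel-density Gaussian-mixture dating of duplication events,
    Ruzzo-Tompa maximal-scoring-segment scanning with bootstrap
    significance for conversion tracts, and the downstream genome,
    expression and gene-ontology statistics. Ships a codon-level
    simulator of quartets, genome pairs and expression tables with
    full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    igraph,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
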