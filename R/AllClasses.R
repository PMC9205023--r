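#' @title Core S4 classes
#' @name quartetconv-classes
#' @description S4 containers for the central objects of the pipeline:
#' gene catalogs, codon alignments, collinear block sets, gene quartets
#' and fitted Ks mixtures.
NULL

#' CodonAlignment: an in-frame nucleotide alignment
#'
#' Holds one or more aligned coding sequences in which gaps (`-`) occur
#' only in whole-codon units, together with the map from alignment
#' columns back to each sequence's ungapped nucleotide coordinates.
#'
#' @slot aln A named [Biostrings::DNAStringSet] of equal-width aligned
#'   sequences; width divisible by 3.
#' @slot maps A named list, one integer vector per sequence, giving for
#'   every alignment nucleotide column the 1-based ungapped position in
#'   that sequence, or `NA` at gap columns.
#' @exportClass CodonAlignment
setClass("CodonAlignment",
  representation(aln = "DNAStringSet", maps = "list"))

setValidity("CodonAlignment", function(object) {
  w <- Biostrings::width(object@aln)
  if (length(unique(w)) > 1) return("aligned sequences differ in width")
  if (length(w) && w[1] %% 3 != 0) return("alignment width not divisible by 3")
  if (!identical(names(object@aln), names(object@maps)))
    return("maps must be named like the alignment")
  TRUE
})

#' GeneCatalog: genes of one genome with coordinates and CDS
#'
#' A genome's gene complement: genomic spans (1-based inclusive, the
#' GFF3 convention, carried natively by [GenomicRanges::GRanges]), a
#' per-chromosome gene-order index, and the strand-resolved CDS of every
#' gene.
#'
#' @slot genes A [GenomicRanges::GRanges] with metadata columns
#'   `gene_id` and `order_index` (0-based rank along each chromosome by
#'   ascending start).
#' @slot cds A named [Biostrings::DNAStringSet], one CDS per gene, in the
#'   same order as `genes`; widths divisible by 3, alphabet A/C/G/T/N.
#' @slot genome A single character label for the genome.
#' @exportClass GeneCatalog
setClass("GeneCatalog",
  representation(genes = "GRanges", cds = "DNAStringSet",
                 genome = "character"))

setValidity("GeneCatalog", function(object) {
  ids <- object@genes$gene_id
  if (anyDuplicated(ids)) return("duplicate gene_id in catalog")
  if (!identical(names(object@cds), ids))
    return("cds names must match gene_id order")
  if (length(object@cds)) {
    if (any(Biostrings::width(object@cds) %% 3 != 0))
      return("CDS length not divisible by 3")
    freq <- Biostrings::alphabetFrequency(object@cds, baseOnly = FALSE)
    bad <- rowSums(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"),
                        drop = FALSE])
    if (any(bad > 0)) return("CDS contains letters outside A/C/G/T/N")
  }
  if (length(object@genome) != 1) return("genome must be a single label")
  TRUE
})

#' CollinearBlockSet: chained collinear blocks and their anchors
#'
#' @slot blocks data.frame with one row per block: `block_id`,
#'   `genome_a`, `genome_b`, `chrom_a`, `chrom_b`, `orientation`
#'   (`+`/`-`), `n_anchors`, `median_ks`, `event_label`.
#' @slot anchors data.frame with one row per anchored homolog pair:
#'   `block_id`, `gene_a`, `gene_b`, `order_a`, `order_b`.
#' @exportClass CollinearBlockSet
setClass("CollinearBlockSet",
  representation(blocks = "data.frame", anchors = "data.frame"))

setValidity("CollinearBlockSet", function(object) {
  if (!all(object@anchors$block_id %in% object@blocks$block_id))
    return("anchor rows reference unknown block_id")
  TRUE
})

#' GeneQuartet: paralogs P1,P2 plus orthologs S1,S2
#'
#' The unit of conversion inference: a duplicate pair P1,P2 from one
#' genome and their respective orthologs S1,S2 from a second genome,
#' with a shared four-way codon alignment and the six pairwise
#' substitution statistics.
#'
#' @slot id Quartet identifier.
#' @slot genes Named character of length 4 (`P1`,`P2`,`S1`,`S2`).
#' @slot alignment The four-way [CodonAlignment-class].
#' @slot pairStats data.frame of six rows (one per gene pair) as
#'   returned by [ng86()].
#' @slot paralogSide Which genome's paralog pair is block-anchored:
#'   `"A"`, `"B"` or `"both"`.
#' @slot provenance Character vector of source block ids.
#' @exportClass GeneQuartet
setClass("GeneQuartet",
  representation(id = "character", genes = "character",
                 alignment = "CodonAlignment", pairStats = "data.frame",
                 paralogSide = "character", provenance = "character"))

setValidity("GeneQuartet", function(object) {
  if (!identical(names(object@genes), c("P1", "P2", "S1", "S2")))
    return("genes must be named P1, P2, S1, S2")
  TRUE
})

#' KsMixtureFit: Gaussian-mixture fit to a Ks density curve
#'
#' @slot bandwidth Kernel bandwidth used for the density curve.
#' @slot grid,density The kernel density curve the mixture was fitted to.
#' @slot components data.frame (`weight`, `mean`, `sd`), sorted by mean.
#' @slot rSquared Goodness of fit of the mixture curve to the KDE curve.
#' @slot converged FALSE when the R-squared threshold was not reached at
#'   the maximum number of components.
#' @exportClass KsMixtureFit
setClass("KsMixtureFit",
  representation(bandwidth = "numeric", grid = "numeric",
                 density = "numeric", components = "data.frame",
                 rSquared = "numeric", converged = "logical"))

setValidity("KsMixtureFit", function(object) {
  cm <- object@components
  if (nrow(cm)) {
    if (any(cm$weight <= 0)) return("component weights must be positive")
    if (any(cm$sd <= 0)) return("component sds must be positive")
  }
  if (object@rSquared > 1 + 1e-8) return("rSquared above 1")
  TRUE
})
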