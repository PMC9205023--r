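#' @describeIn GeneCatalog-accessors Gene identifiers, in catalog order.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @describeIn GeneCatalog-accessors CDS sequences as a named DNAStringSet.
#' @export
setGeneric("cdsSeqs", function(x) standardGeneric("cdsSeqs"))

#' @describeIn GeneCatalog-accessors Gene coordinates as a GRanges.
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @describeIn GeneCatalog-accessors Genome label.
#' @export
setGeneric("genomeLabel", function(x) standardGeneric("genomeLabel"))

#' @describeIn GeneCatalog-accessors Per-chromosome 0-based gene order.
#' @export
setGeneric("orderIndex", function(x) standardGeneric("orderIndex"))

#' Accessors for GeneCatalog
#'
#' @param x A [GeneCatalog-class].
#' @name GeneCatalog-accessors
#' @aliases geneIds cdsSeqs geneRanges genomeLabel orderIndex
NULL

setMethod("geneIds", "GeneCatalog", function(x) x@genes$gene_id)
setMethod("cdsSeqs", "GeneCatalog", function(x) x@cds)
setMethod("geneRanges", "GeneCatalog", function(x) x@genes)
setMethod("genomeLabel", "GeneCatalog", function(x) x@genome)
setMethod("orderIndex", "GeneCatalog",
  function(x) setNames(x@genes$order_index, x@genes$gene_id))

#' @export
setMethod("length", "GeneCatalog", function(x) length(x@genes))

setMethod("show", "GeneCatalog", function(object) {
  cat("GeneCatalog:", object@genome, "-", length(object@genes), "genes on",
      length(unique(as.character(GenomicRanges::seqnames(object@genes)))),
      "chromosomes\n")
})

#' Alignment accessors
#'
#' @param x A [CodonAlignment-class] or [GeneQuartet-class].
#' @name alignment-accessors
#' @aliases alignedSeqs columnMaps
NULL

#' @describeIn alignment-accessors Aligned sequences (DNAStringSet).
#' @export
setGeneric("alignedSeqs", function(x) standardGeneric("alignedSeqs"))

#' @describeIn alignment-accessors Column-to-ungapped-coordinate maps.
#' @export
setGeneric("columnMaps", function(x) standardGeneric("columnMaps"))

setMethod("alignedSeqs", "CodonAlignment", function(x) x@aln)
setMethod("columnMaps", "CodonAlignment", function(x) x@maps)
setMethod("alignedSeqs", "GeneQuartet", function(x) x@alignment@aln)
setMethod("columnMaps", "GeneQuartet", function(x) x@alignment@maps)

#' @export
setMethod("length", "CodonAlignment", function(x) length(x@aln))

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment:", length(object@aln), "sequences x",
      ifelse(length(object@aln), Biostrings::width(object@aln)[1], 0),
      "nt columns\n")
})

#' Block set accessors
#'
#' @param x A [CollinearBlockSet-class].
#' @name blockset-accessors
#' @aliases blockTable anchorTable
NULL

#' @describeIn blockset-accessors One row per block.
#' @export
setGeneric("blockTable", function(x) standardGeneric("blockTable"))

#' @describeIn blockset-accessors One row per anchored homolog pair.
#' @export
setGeneric("anchorTable", function(x) standardGeneric("anchorTable"))

setMethod("blockTable", "CollinearBlockSet", function(x) x@blocks)
setMethod("anchorTable", "CollinearBlockSet", function(x) x@anchors)

#' @export
setMethod("length", "CollinearBlockSet", function(x) nrow(x@blocks))

setMethod("show", "CollinearBlockSet", function(object) {
  cat("CollinearBlockSet:", nrow(object@blocks), "blocks,",
      nrow(object@anchors), "anchors\n")
  if (nrow(object@blocks)) {
    tab <- table(object@blocks$event_label, useNA = "ifany")
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

#' Quartet accessors
#'
#' @param x A [GeneQuartet-class].
#' @name quartet-accessors
#' @aliases quartetId quartetGenes pairStats paralogSide
NULL

#' @describeIn quartet-accessors Quartet identifier.
#' @export
setGeneric("quartetId", function(x) standardGeneric("quartetId"))

#' @describeIn quartet-accessors Named gene ids (P1, P2, S1, S2).
#' @export
setGeneric("quartetGenes", function(x) standardGeneric("quartetGenes"))

#' @describeIn quartet-accessors Six-row pairwise statistics table.
#' @export
setGeneric("pairStats", function(x) standardGeneric("pairStats"))

#' @describeIn quartet-accessors Which genome's paralogs are block-anchored.
#' @export
setGeneric("paralogSide", function(x) standardGeneric("paralogSide"))

setMethod("quartetId", "GeneQuartet", function(x) x@id)
setMethod("quartetGenes", "GeneQuartet", function(x) x@genes)
setMethod("pairStats", "GeneQuartet", function(x) x@pairStats)
setMethod("paralogSide", "GeneQuartet", function(x) x@paralogSide)

setMethod("show", "GeneQuartet", function(object) {
  cat("GeneQuartet", object@id, "\n  P1/P2:", object@genes[["P1"]], "/",
      object@genes[["P2"]], "\n  S1/S2:", object@genes[["S1"]], "/",
      object@genes[["S2"]], "\n")
  ps <- object@pairStats
  if (nrow(ps)) {
    kk <- ps$ks[match(c("P1:P2", "P1:S1", "P2:S2"),
                      paste(ps$gene_a, ps$gene_b, sep = ":"))]
    cat("  Ks(P1,P2) =", signif(kk[1], 3), " Ks(P1,S1) =", signif(kk[2], 3),
        " Ks(P2,S2) =", signif(kk[3], 3), "\n")
  }
})

#' Mixture fit accessors
#'
#' @param x A [KsMixtureFit-class].
#' @name ksmixture-accessors
#' @aliases mixtureComponents mixtureRSquared
NULL

#' @describeIn ksmixture-accessors Component table (weight, mean, sd).
#' @export
setGeneric("mixtureComponents", function(x) standardGeneric("mixtureComponents"))

#' @describeIn ksmixture-accessors Curve-level R-squared of the fit.
#' @export
setGeneric("mixtureRSquared", function(x) standardGeneric("mixtureRSquared"))

setMethod("mixtureComponents", "KsMixtureFit", function(x) x@components)
setMethod("mixtureRSquared", "KsMixtureFit", function(x) x@rSquared)

setMethod("show", "KsMixtureFit", function(object) {
  cat("KsMixtureFit:", nrow(object@components), "component(s), R2 =",
      round(object@rSquared, 4),
      if (!object@converged) "(threshold not reached)" else "", "\n")
  for (i in seq_len(nrow(object@components)))
    cat(sprintf("  w=%.3f mean=%.4f sd=%.4f\n",
                object@components$weight[i], object@components$mean[i],
                object@components$sd[i]))
})
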