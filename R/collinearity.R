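# Chaining homolog pairs into collinear blocks on gene-order
# coordinates, and labeling blocks by polyploidy event from their
# anchor Ks.

#' Remove pairs touching large gene families
#'
#' Families are the connected components of the homology graph spanned
#' by the pair table; every pair touching a component with
#' `family_size_cutoff` or more member genes is removed.
#'
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param family_size_cutoff Minimum family size to trigger removal.
#' @return The filtered pair table.
#' @export
filterLargeFamilies <- function(pairs, family_size_cutoff = 50) {
  if (nrow(pairs) == 0) return(pairs)
  g <- igraph::graph_from_data_frame(pairs[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  size_of <- comp$csize[comp$membership]
  names(size_of) <- names(comp$membership)
  big <- size_of >= family_size_cutoff
  drop <- big[pairs$gene_a] | big[pairs$gene_b]
  pairs[!drop, , drop = FALSE]
}

#' Apply homology-search quality filters when columns are present
#'
#' If the pair table carries `evalue` and/or `score` columns, rows are
#' filtered to `evalue < max_evalue` and `score > min_score`; otherwise
#' the table is returned unchanged.
#'
#' @param pairs Pair table.
#' @param max_evalue,min_score Thresholds.
#' @export
filterPairQuality <- function(pairs, max_evalue = 1e-5, min_score = 100) {
  if (!is.null(pairs$evalue)) pairs <- pairs[pairs$evalue < max_evalue, ]
  if (!is.null(pairs$score)) pairs <- pairs[pairs$score > min_score, ]
  pairs
}

# Longest gap-constrained monotone chain among anchor points, by
# quadratic DP. Points: data.frame(x, y, idx). Returns integer indices
# into the points (in chain order) of one best chain; ties broken by the
# smaller starting x, then y.
.bestChain <- function(x, y, max_gap) {
  n <- length(x)
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  f <- rep(1L, n); parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] < x[i] && y[j] < y[i] &&
          x[i] - x[j] <= max_gap && y[i] - y[j] <= max_gap &&
          f[j] + 1L > f[i]) {
        f[i] <- f[j] + 1L
        parent[i] <- j
      }
    }
  }
  best <- max(f)
  ends <- which(f == best)
  # reconstruct all best chains' starts to apply the tie-break
  chains <- lapply(ends, function(e) {
    ch <- e
    while (!is.na(parent[ch[1]])) ch <- c(parent[ch[1]], ch)
    ch
  })
  starts_x <- vapply(chains, function(ch) x[ch[1]], numeric(1))
  starts_y <- vapply(chains, function(ch) y[ch[1]], numeric(1))
  pick <- order(starts_x, starts_y)[1]
  ord[chains[[pick]]]
}

#' Chain homolog pairs into collinear blocks
#'
#' Within every chromosome pair and orientation, repeatedly extracts the
#' highest-scoring chain of anchors with strictly monotone gene order on
#' both genomes and at most `max_gap` intervening genes between adjacent
#' anchors on either genome (score = number of anchors; ties broken by
#' the smaller starting order index). Extracted anchors are removed, so
#' blocks never share an anchor pair. Chains shorter than
#' `min_block_len` are discarded.
#'
#' @param pairs data.frame `gene_a`, `gene_b` (canonicalized).
#' @param catalog_a,catalog_b [GeneCatalog-class] objects; pass the same
#'   catalog twice for an intra-genome scan.
#' @param max_gap Maximum intervening genes between adjacent anchors.
#' @param min_block_len Minimum anchors per block.
#' @return A [CollinearBlockSet-class] (median_ks NA, label UNASSIGNED).
#' @export
chainCollinearPairs <- function(pairs, catalog_a, catalog_b = catalog_a,
                                max_gap = 50, min_block_len = 4) {
  intra <- identical(genomeLabel(catalog_a), genomeLabel(catalog_b))
  ga <- geneRanges(catalog_a); gb <- geneRanges(catalog_b)
  lk_a <- data.frame(chrom = as.character(GenomicRanges::seqnames(ga)),
                     ord = ga$order_index, row.names = ga$gene_id)
  lk_b <- data.frame(chrom = as.character(GenomicRanges::seqnames(gb)),
                     ord = gb$order_index, row.names = gb$gene_id)
  a_in <- pairs$gene_a %in% rownames(lk_a) & pairs$gene_b %in% rownames(lk_b)
  b_in <- pairs$gene_a %in% rownames(lk_b) & pairs$gene_b %in% rownames(lk_a)
  use <- if (intra) a_in else (a_in | b_in)
  pr <- pairs[use, , drop = FALSE]
  if (nrow(pr) == 0)
    return(methods::new("CollinearBlockSet",
                        blocks = .emptyBlocks(), anchors = .emptyAnchors()))
  # orient pairs so gene_a belongs to catalog_a
  if (!intra) {
    flip <- !(pr$gene_a %in% rownames(lk_a) & pr$gene_b %in% rownames(lk_b))
    tmp <- pr$gene_a[flip]; pr$gene_a[flip] <- pr$gene_b[flip]
    pr$gene_b[flip] <- tmp
  }
  an <- data.frame(gene_a = pr$gene_a, gene_b = pr$gene_b,
                   chrom_a = lk_a[pr$gene_a, "chrom"],
                   ord_a = lk_a[pr$gene_a, "ord"],
                   chrom_b = lk_b[pr$gene_b, "chrom"],
                   ord_b = lk_b[pr$gene_b, "ord"],
                   stringsAsFactors = FALSE)
  if (intra) {
    # canonical orientation within one genome: lower chromosome (then
    # order) on the a-side, so mirrored pairs chain identically
    flip <- an$chrom_a > an$chrom_b |
      (an$chrom_a == an$chrom_b & an$ord_a > an$ord_b)
    an[flip, c("gene_a", "gene_b", "chrom_a", "ord_a", "chrom_b", "ord_b")] <-
      an[flip, c("gene_b", "gene_a", "chrom_b", "ord_b", "chrom_a", "ord_a")]
  }
  blocks <- list(); anchors <- list(); bid <- 0
  for (key in unique(paste(an$chrom_a, an$chrom_b))) {
    sub <- an[paste(an$chrom_a, an$chrom_b) == key, , drop = FALSE]
    repeat {
      if (nrow(sub) < min_block_len) break
      fwd <- .bestChain(sub$ord_a, sub$ord_b, max_gap)
      rev_ <- .bestChain(sub$ord_a, -sub$ord_b, max_gap)
      take <- if (length(fwd) >= length(rev_)) list(fwd, "+") else
        list(rev_, "-")
      if (length(take[[1]]) < min_block_len) break
      bid <- bid + 1
      idx <- take[[1]]
      blocks[[bid]] <- data.frame(
        block_id = sprintf("blk%04d", bid),
        genome_a = genomeLabel(catalog_a), genome_b = genomeLabel(catalog_b),
        chrom_a = sub$chrom_a[1], chrom_b = sub$chrom_b[1],
        orientation = take[[2]], n_anchors = length(idx),
        median_ks = NA_real_, event_label = "UNASSIGNED",
        stringsAsFactors = FALSE)
      anchors[[bid]] <- data.frame(
        block_id = sprintf("blk%04d", bid),
        gene_a = sub$gene_a[idx], gene_b = sub$gene_b[idx],
        order_a = sub$ord_a[idx], order_b = sub$ord_b[idx],
        stringsAsFactors = FALSE)
      sub <- sub[-idx, , drop = FALSE]
    }
  }
  if (bid == 0)
    return(methods::new("CollinearBlockSet",
                        blocks = .emptyBlocks(), anchors = .emptyAnchors()))
  methods::new("CollinearBlockSet",
               blocks = do.call(rbind, blocks),
               anchors = do.call(rbind, anchors))
}

.emptyBlocks <- function() data.frame(
  block_id = character(0), genome_a = character(0), genome_b = character(0),
  chrom_a = character(0), chrom_b = character(0), orientation = character(0),
  n_anchors = integer(0), median_ks = numeric(0), event_label = character(0),
  stringsAsFactors = FALSE)

.emptyAnchors <- function() data.frame(
  block_id = character(0), gene_a = character(0), gene_b = character(0),
  order_a = integer(0), order_b = integer(0), stringsAsFactors = FALSE)

.pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Annotate blocks with the median Ks of their anchors
#'
#' @param blockset A [CollinearBlockSet-class].
#' @param pairstats data.frame with `gene_a`, `gene_b`, `ks` (e.g.
#'   row-bound [ng86()] results); saturated/missing anchor Ks are
#'   skipped. A block whose anchors are all missing keeps `median_ks`
#'   NA and the label UNASSIGNED.
#' @return The block set with `median_ks` filled in.
#' @export
annotateBlocksKs <- function(blockset, pairstats) {
  an <- anchorTable(blockset)
  bl <- blockTable(blockset)
  ks <- setNames(pairstats$ks, .pairKey(pairstats$gene_a, pairstats$gene_b))
  an_ks <- ks[.pairKey(an$gene_a, an$gene_b)]
  med <- tapply(an_ks, an$block_id, function(v) {
    v <- v[is.finite(v)]
    if (length(v)) median(v) else NA_real_
  })
  bl$median_ks <- as.numeric(med[bl$block_id])
  methods::new("CollinearBlockSet", blocks = bl, anchors = an)
}

#' Label blocks by polyploidy/speciation event windows
#'
#' @param blockset A Ks-annotated [CollinearBlockSet-class].
#' @param windows data.frame `event`, `lo`, `hi` of disjoint Ks
#'   intervals (e.g. from [peaksToEventWindows()]).
#' @return The block set with `event_label` set to the window containing
#'   each block's median Ks, or `UNASSIGNED`.
#' @export
labelBlocksByEvent <- function(blockset, windows) {
  if (nrow(windows) > 1) {
    w <- windows[order(windows$lo), ]
    if (any(w$hi[-nrow(w)] > w$lo[-1]))
      stop("event windows overlap")
  }
  bl <- blockTable(blockset)
  bl$event_label <- "UNASSIGNED"
  for (i in seq_len(nrow(windows))) {
    hit <- !is.na(bl$median_ks) & bl$median_ks >= windows$lo[i] &
      bl$median_ks <= windows$hi[i]
    bl$event_label[hit] <- windows$event[i]
  }
  methods::new("CollinearBlockSet", blocks = bl,
               anchors = anchorTable(blockset))
}
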