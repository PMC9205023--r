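# Assembly of homologous gene quartets from SCT-labeled paralog blocks
# and ortholog blocks, reliability filtering, and four-taxon topology
# classification.

.PAIRSET <- list(c("P1", "P2"), c("S1", "S2"), c("P1", "S1"),
                 c("P2", "S2"), c("P1", "S2"), c("P2", "S1"))

#' Assemble a GeneQuartet directly from four CDS sequences
#'
#' Builds the shared four-way codon alignment and the six pairwise NG86
#' statistics from raw coding sequences, without gene catalogs.
#'
#' @param cds Named character vector or DNAStringSet with elements
#'   `P1`, `P2` (the paralogs) and `S1`, `S2` (their orthologs).
#' @param id Quartet identifier.
#' @param paralogSide Which genome's paralog pair is under test.
#' @return A [GeneQuartet-class].
#' @examples
#' sim <- simulateQuartet(quartetSimConfig(n_codons = 100), seed = 1)
#' q <- quartetFromCds(as.character(sim$seqs))
#' pairStats(q)[, c("gene_a", "gene_b", "ks")]
#' @export
quartetFromCds <- function(cds, id = "q1", paralogSide = "A") {
  cds <- setNames(as.character(Biostrings::DNAStringSet(cds)), names(cds))
  stopifnot(all(c("P1", "P2", "S1", "S2") %in% names(cds)))
  aln <- quartetAlign(cds)
  ps <- do.call(rbind, lapply(.PAIRSET, function(p) ng86(aln, p)))
  methods::new("GeneQuartet", id = id,
               genes = c(P1 = "P1", P2 = "P2", S1 = "S1", S2 = "S2"),
               alignment = aln, pairStats = ps,
               paralogSide = paralogSide, provenance = character(0))
}

#' Assemble a GeneQuartet from four gene ids
#'
#' Builds the shared four-way codon alignment (via [quartetAlign()]) and
#' the six pairwise NG86 statistics.
#'
#' @param p1,p2,s1,s2 Gene ids: paralogs of genome A and their
#'   respective orthologs in genome B.
#' @param catalog_a,catalog_b Catalogs supplying the CDS.
#' @param id Quartet identifier.
#' @param paralogSide Which genome's paralog pair is block-anchored.
#' @param provenance Source block ids.
#' @return A [GeneQuartet-class].
#' @export
makeQuartet <- function(p1, p2, s1, s2, catalog_a, catalog_b,
                        id = paste(p1, p2, sep = "|"),
                        paralogSide = "A", provenance = character(0)) {
  cds <- c(P1 = as.character(cdsSeqs(catalog_a)[[p1]]),
           P2 = as.character(cdsSeqs(catalog_a)[[p2]]),
           S1 = as.character(cdsSeqs(catalog_b)[[s1]]),
           S2 = as.character(cdsSeqs(catalog_b)[[s2]]))
  aln <- quartetAlign(cds)
  ps <- do.call(rbind, lapply(.PAIRSET, function(p) ng86(aln, p)))
  methods::new("GeneQuartet", id = id,
               genes = c(P1 = p1, P2 = p2, S1 = s1, S2 = s2),
               alignment = aln, pairStats = ps,
               paralogSide = paralogSide, provenance = provenance)
}

# gene (genome A) -> best ortholog (genome B) lookup from ortholog
# blocks: prefer the anchor in the longest block, then the
# lexicographically smallest partner id
.orthologLookup <- function(ortholog_blocks, a_side = "gene_a") {
  an <- anchorTable(ortholog_blocks)
  bl <- blockTable(ortholog_blocks)
  if (nrow(an) == 0) return(list())
  an$len <- bl$n_anchors[match(an$block_id, bl$block_id)]
  b_side <- setdiff(c("gene_a", "gene_b"), a_side)
  an <- an[order(an[[a_side]], -an$len, an[[b_side]]), ]
  an <- an[!duplicated(an[[a_side]]), ]
  setNames(split(an[, c(b_side, "block_id")], seq_len(nrow(an))),
           an[[a_side]])
}

#' Build homologous gene quartets from labeled blocks
#'
#' For every anchor pair (P1, P2) of an SCT-labeled paralog block of
#' genome A, looks up the orthologs S1 of P1 and S2 of P2 among the
#' anchors of ORTHOLOG-labeled blocks and emits a quartet when both
#' exist; at most one quartet per paralog pair (ties between ortholog
#' anchors resolved by the longest block, then lexicographic gene id).
#' Paralog blocks of genome B are scanned symmetrically, the quartet
#' still being recorded as P1,P2 (genome A) / S1,S2 (genome B); a
#' quartet whose paralog pair is anchored on both sides is emitted once
#' with `paralogSide = "both"`.
#'
#' @param paralog_blocks_a,paralog_blocks_b Labeled intra-genome
#'   [CollinearBlockSet-class]s (either may be NULL).
#' @param ortholog_blocks Labeled inter-genome block set (genome A on
#'   the a-side).
#' @param catalog_a,catalog_b Gene catalogs.
#' @param sct_label,ortholog_label Event labels selecting the blocks.
#' @return List of [GeneQuartet-class] objects.
#' @export
buildQuartets <- function(paralog_blocks_a, paralog_blocks_b,
                          ortholog_blocks, catalog_a, catalog_b,
                          sct_label = "SCT", ortholog_label = "ORTHOLOG") {
  keepOrth <- function(bs) {
    bl <- blockTable(bs)
    keep <- bl$block_id[bl$event_label == ortholog_label]
    methods::new("CollinearBlockSet",
                 blocks = bl[bl$event_label == ortholog_label, ],
                 anchors = anchorTable(bs)[anchorTable(bs)$block_id %in%
                                             keep, ])
  }
  ob <- keepOrth(ortholog_blocks)
  a2b <- .orthologLookup(ob, "gene_a")
  sctAnchors <- function(bs) {
    if (is.null(bs)) return(.emptyAnchors())
    bl <- blockTable(bs)
    keep <- bl$block_id[bl$event_label == sct_label]
    anchorTable(bs)[anchorTable(bs)$block_id %in% keep, , drop = FALSE]
  }
  found <- new.env(parent = emptyenv())
  quartets <- list()
  addQuartet <- function(p1, p2, s1, s2, side, prov) {
    key <- paste(sort(c(p1, p2)), collapse = "|")
    if (!is.null(found[[key]])) {
      i <- found[[key]]
      q <- quartets[[i]]
      if (q@paralogSide != side) q@paralogSide <- "both"
      q@provenance <- unique(c(q@provenance, prov))
      quartets[[i]] <<- q
      return(invisible(NULL))
    }
    q <- makeQuartet(p1, p2, s1, s2, catalog_a, catalog_b,
                     id = sprintf("qt%04d", length(quartets) + 1L),
                     paralogSide = side, provenance = prov)
    quartets[[length(quartets) + 1L]] <<- q
    found[[key]] <- length(quartets)
    invisible(NULL)
  }
  anA <- sctAnchors(paralog_blocks_a)
  for (i in seq_len(nrow(anA))) {
    p1 <- anA$gene_a[i]; p2 <- anA$gene_b[i]
    o1 <- a2b[[p1]]; o2 <- a2b[[p2]]
    if (is.null(o1) || is.null(o2)) next
    addQuartet(p1, p2, o1$gene_b, o2$gene_b, "A",
               c(anA$block_id[i], o1$block_id, o2$block_id))
  }
  b2a <- .orthologLookup(ob, "gene_b")
  anB <- sctAnchors(paralog_blocks_b)
  for (i in seq_len(nrow(anB))) {
    s1 <- anB$gene_a[i]; s2 <- anB$gene_b[i]
    o1 <- b2a[[s1]]; o2 <- b2a[[s2]]
    if (is.null(o1) || is.null(o2)) next
    addQuartet(o1$gene_a, o2$gene_a, s1, s2, "B",
               c(anB$block_id[i], o1$block_id, o2$block_id))
  }
  quartets
}

#' Reliability filter for a quartet
#'
#' Drops highly divergent quartets: any gene pair with a gap fraction
#' above `max_gap_fraction` (default 50% of the alignment length) or an
#' amino-acid identity below `min_aa_identity` (default 40%).
#'
#' @param quartet A [GeneQuartet-class].
#' @param max_gap_fraction,min_aa_identity Thresholds.
#' @return List `keep` (logical) and `reason` (`NA` when kept).
#' @export
filterQuartet <- function(quartet, max_gap_fraction = 0.5,
                          min_aa_identity = 0.4) {
  ps <- pairStats(quartet)
  if (any(ps$gap_fraction > max_gap_fraction))
    return(list(keep = FALSE, reason = "gap>50%"))
  if (any(is.na(ps$aa_identity)) || any(ps$aa_identity < min_aa_identity))
    return(list(keep = FALSE, reason = "identity<40%"))
  list(keep = TRUE, reason = NA_character_)
}

# Six pairwise distances -> symmetric 4x4 matrix (taxa P1,P2,S1,S2)
.quartetDistMatrix <- function(d) {
  taxa <- c("P1", "P2", "S1", "S2")
  m <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  for (p in .PAIRSET) {
    key <- paste(p, collapse = ":")
    m[p[1], p[2]] <- m[p[2], p[1]] <- d[[key]]
  }
  m
}

#' Four-taxon topology of a quartet
#'
#' Builds the 4x4 Jukes-Cantor nucleotide distance matrix over the
#' alignment columns shared by all four genes and classifies the
#' neighbor-joining tree: `expected` pairs each paralog with its
#' ortholog (((P1,S1),(P2,S2))), `paralogs_sister` pairs the paralogs
#' (((P1,P2),(S1,S2))), `mixed` is the remaining topology, and
#' `undetermined` is returned when any distance is saturated or the
#' internal edge is absent.
#'
#' @param x A [GeneQuartet-class], or a named numeric vector of the six
#'   pairwise distances (`"P1:P2"`, `"S1:S2"`, `"P1:S1"`, `"P2:S2"`,
#'   `"P1:S2"`, `"P2:S1"`).
#' @return One of `"expected"`, `"paralogs_sister"`, `"mixed"`,
#'   `"undetermined"`.
#' @export
quartetTopology <- function(x) {
  d <- if (methods::is(x, "GeneQuartet")) quartetNucDistances(x) else x
  if (any(!is.finite(unlist(d)))) return("undetermined")
  m <- .quartetDistMatrix(as.list(d))
  tr <- ape::nj(m)
  tip <- which(tr$tip.label == "P1")
  node <- tr$edge[tr$edge[, 2] == tip, 1]
  sibs <- tr$edge[tr$edge[, 1] == node & tr$edge[, 2] <= 4, 2]
  partner <- setdiff(sibs, tip)
  if (length(partner) != 1) return("undetermined")
  switch(tr$tip.label[partner],
         S1 = "expected", P2 = "paralogs_sister", S2 = "mixed")
}

#' Jukes-Cantor nucleotide distances of the six quartet pairs
#'
#' Computed over the alignment columns where all four genes carry an
#' unambiguous base, so the six distances share a common site set.
#'
#' @param quartet A [GeneQuartet-class].
#' @return Named numeric vector (names like `"P1:P2"`).
#' @export
quartetNucDistances <- function(quartet) {
  cm <- .quartetCharMatrix(quartet)
  ok <- cm$ok
  vapply(.PAIRSET, function(p) {
    pdiff <- mean(cm$chars[ok, p[1]] != cm$chars[ok, p[2]])
    jcCorrect(pdiff)
  }, numeric(1)) -> d
  names(d) <- vapply(.PAIRSET, paste, character(1), collapse = ":")
  d
}

# character matrix of the alignment plus the all-four-valid column mask
.quartetCharMatrix <- function(quartet) {
  seqs <- as.character(alignedSeqs(quartet))
  chars <- vapply(seqs, function(s) strsplit(s, "")[[1]],
                  character(nchar(seqs[1])))
  valid <- chars %in% BASES
  dim(valid) <- dim(chars)
  list(chars = chars, ok = rowSums(valid) == ncol(chars))
}
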