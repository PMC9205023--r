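# Whole-gene (WCV) and partial-gene (PCV) conversion calling within
# quartets. PCV: per-column difference profiles of the paralog pair and
# the two ortholog pairs are combined into a score array (mean ortholog
# difference minus paralog difference), scanned for maximal-scoring
# segments (Ruzzo-Tompa), tested by a column bootstrap, then masked and
# rescanned recursively. WCV: the paralog Ks must undercut both ortholog
# Ks and the bootstrap-supported NJ topology must pair the paralogs.

#' Per-column difference profiles of a quartet
#'
#' For each gene pair an integer array over the shared alignment
#' columns: 0 where the bases match, 1 where they differ, NA at columns
#' where any of the four genes carries a gap or ambiguous base (so all
#' profiles share one site set).
#'
#' @param quartet A [GeneQuartet-class].
#' @return List of integer vectors `P1P2`, `S1S2`, `P1S1`, `P2S2`.
#' @export
siteProfiles <- function(quartet) {
  cm <- .quartetCharMatrix(quartet)
  prof <- function(a, b) {
    p <- as.integer(cm$chars[, a] != cm$chars[, b])
    p[!cm$ok] <- NA_integer_
    p
  }
  list(P1P2 = prof("P1", "P2"), S1S2 = prof("S1", "S2"),
       P1S1 = prof("P1", "S1"), P2S2 = prof("P2", "S2"))
}

#' Conversion score array
#'
#' Per column, the mean of the two ortholog difference profiles minus
#' the paralog profile: positive where the paralogs agree but the
#' orthologs do not (the conversion signature), negative where the
#' paralogs disagree. Missing columns score 0. Values lie in
#' \{-1, -0.5, 0, +0.5, +1\}.
#'
#' @param par_profile Paralog pair profile (0/1/NA).
#' @param orth1,orth2 The two ortholog pair profiles.
#' @return Numeric score vector.
#' @export
conversionScoreArray <- function(par_profile, orth1, orth2) {
  stopifnot(length(par_profile) == length(orth1),
            length(orth1) == length(orth2))
  o <- rowMeans(cbind(orth1, orth2), na.rm = TRUE)
  s <- o - par_profile
  s[!is.finite(s)] <- 0
  s
}

#' Maximal-scoring segments of a score array
#'
#' All maximal-scoring subsequences (Ruzzo & Tompa 1999) with positive
#' total score, discarding segments spanning fewer than `min_tract_len`
#' columns.
#'
#' @param scores Numeric score vector.
#' @param min_tract_len Minimum segment span in columns (default 10).
#' @return data.frame `start`, `end` (1-based inclusive columns),
#'   `score`, ordered by start.
#' @export
maximalScoringSegments <- function(scores, min_tract_len = 10) {
  m <- .rt_segments_cpp(as.numeric(scores))
  df <- as.data.frame(m)
  df[df$end - df$start + 1 >= min_tract_len, , drop = FALSE]
}

#' Bootstrap p-value of a segment score
#'
#' The null distribution is built by resampling the columns of the
#' score array with replacement `B` times and recording each
#' replicate's best maximal-scoring segment spanning at least
#' `min_tract_len` columns. The p-value is the add-one-corrected
#' proportion of replicates reaching the observed score:
#' `(1 + #\{best >= observed\}) / (B + 1)`.
#'
#' @param scores Numeric score vector (the array the segment came from).
#' @param segment_score Observed segment score.
#' @param B Bootstrap replicates (default 1000; below 100 a warning).
#' @param min_tract_len Minimum qualifying segment span.
#' @return p-value in `(0, 1]`.
#' @export
bootstrapSegmentP <- function(scores, segment_score, B = 1000,
                              min_tract_len = 10) {
  if (B < 100) warning("B < 100 gives a coarse bootstrap p-value")
  null_best <- .boot_max_seg_cpp(as.numeric(scores), as.integer(B),
                                 as.integer(min_tract_len))
  null_best[!is.finite(null_best)] <- 0  # replicates with no segment
  (1 + sum(null_best >= segment_score)) / (B + 1)
}

# map an alignment-column span to the acceptor's ungapped nucleotide
# coordinates (1-based inclusive)
.spanToGene <- function(quartet, gene_label, aln_start, aln_end) {
  map <- columnMaps(quartet)[[gene_label]]
  pos <- map[aln_start:aln_end]
  pos <- pos[!is.na(pos)]
  if (!length(pos)) return(c(NA_integer_, NA_integer_))
  c(min(pos), max(pos))
}

.emptyCalls <- function() data.frame(
  quartet_id = character(0), type = character(0),
  converted_genome = character(0), acceptor = character(0),
  donor = character(0), tract_start = integer(0), tract_end = integer(0),
  aln_start = integer(0), aln_end = integer(0), score = numeric(0),
  p_value = numeric(0), direction_confidence = character(0),
  stringsAsFactors = FALSE)

#' Detect partial-gene conversion (PCV) tracts in a quartet
#'
#' Recursive maximal-segment scan: score the quartet, take the
#' best-scoring qualifying segment, test it by column bootstrap, and if
#' significant emit a call, mask the segment's columns (score 0) and
#' rescan, for at most `max_rounds` rounds. Direction is resolved
#' inside each tract by comparing the two ortholog profiles: the copy
#' whose ortholog comparison holds the tract's mismatches is the
#' acceptor (it carries the overwritten sequence); equal counts give
#' `ambiguous`.
#'
#' @param quartet A filtered [GeneQuartet-class].
#' @param genome Which paralog pair to scan: `"A"` (P1/P2) or `"B"`
#'   (S1/S2).
#' @param min_tract_len Minimum tract span in columns (default 10).
#' @param alpha Significance level for the bootstrap test.
#' @param B Bootstrap replicates.
#' @param max_rounds Recursion cap.
#' @return data.frame of conversion calls (possibly empty); tract
#'   coordinates are 1-based inclusive ungapped positions of the
#'   acceptor.
#' @export
detectPcv <- function(quartet, genome = "A", min_tract_len = 10,
                      alpha = 0.05, B = 1000, max_rounds = 10) {
  prof <- siteProfiles(quartet)
  copies <- if (genome == "A") c("P1", "P2") else c("S1", "S2")
  par_p <- if (genome == "A") prof$P1P2 else prof$S1S2
  o1 <- prof$P1S1   # ortholog pair of copy 1 (P1 or S1)
  o2 <- prof$P2S2   # ortholog pair of copy 2
  scores <- conversionScoreArray(par_p, o1, o2)
  calls <- .emptyCalls()
  for (round in seq_len(max_rounds)) {
    segs <- maximalScoringSegments(scores, min_tract_len)
    if (nrow(segs) == 0) break
    best <- segs[order(-segs$score, segs$start), ][1, ]
    p <- bootstrapSegmentP(scores, best$score, B = B,
                           min_tract_len = min_tract_len)
    if (p > alpha) break
    cols <- best$start:best$end
    m1 <- sum(o1[cols] == 1, na.rm = TRUE)
    m2 <- sum(o2[cols] == 1, na.rm = TRUE)
    if (m1 > m2) {
      acceptor <- copies[1]; donor <- copies[2]; conf <- "resolved"
    } else if (m2 > m1) {
      acceptor <- copies[2]; donor <- copies[1]; conf <- "resolved"
    } else {
      acceptor <- copies[1]; donor <- copies[2]; conf <- "ambiguous"
    }
    tract <- .spanToGene(quartet, acceptor, best$start, best$end)
    calls <- rbind(calls, data.frame(
      quartet_id = quartetId(quartet), type = "PCV",
      converted_genome = genome,
      acceptor = quartetGenes(quartet)[[acceptor]],
      donor = quartetGenes(quartet)[[donor]],
      tract_start = tract[1], tract_end = tract[2],
      aln_start = best$start, aln_end = best$end,
      score = best$score, p_value = p,
      direction_confidence = conf, stringsAsFactors = FALSE))
    scores[cols] <- 0
  }
  calls
}

# per-codon-column mismatch counts for the six pairs, over columns
# valid in all four genes; used by the WCV topology bootstrap
.codonDiffMatrix <- function(quartet) {
  cm <- .quartetCharMatrix(quartet)
  L <- nrow(cm$chars) %/% 3
  cod_ok <- matrix(cm$ok, nrow = 3)
  ok <- colSums(cod_ok) == 3
  diffs <- sapply(.PAIRSET, function(p) {
    d <- cm$chars[, p[1]] != cm$chars[, p[2]]
    colSums(matrix(d, nrow = 3))
  })
  colnames(diffs) <- vapply(.PAIRSET, paste, character(1), collapse = ":")
  list(diffs = diffs[ok, , drop = FALSE], n_codons = sum(ok))
}

.topologyFromDiffs <- function(diff_sums, n_codons) {
  p <- diff_sums / (3 * n_codons)
  d <- jcCorrect(p)
  if (any(!is.finite(d))) return("undetermined")
  s_exp <- d[["P1:S1"]] + d[["P2:S2"]]
  s_sis <- d[["P1:P2"]] + d[["S1:S2"]]
  s_mix <- d[["P1:S2"]] + d[["P2:S1"]]
  lab <- c("expected", "paralogs_sister", "mixed")
  lab[which.min(c(s_exp, s_sis, s_mix))]
}

#' Bootstrap support of the paralogs-sister topology
#'
#' Codon columns are resampled with replacement `B` times; each
#' replicate's four-point topology is recorded and the support is the
#' fraction of replicates pairing the paralogs.
#'
#' @param quartet A [GeneQuartet-class].
#' @param B Bootstrap replicates.
#' @return Support in `[0, 1]`.
#' @export
topologyBootstrapSupport <- function(quartet, B = 1000) {
  dm <- .codonDiffMatrix(quartet)
  n <- dm$n_codons
  if (n < 2) return(0)
  hits <- 0
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    top <- .topologyFromDiffs(colSums(dm$diffs[idx, , drop = FALSE]), n)
    if (top == "paralogs_sister") hits <- hits + 1
  }
  hits / B
}

#' Detect whole-gene conversion (WCV) in a quartet
#'
#' Calls WCV for the scanned genome's paralog pair when (i) the paralog
#' Ks undercuts both ortholog Ks, (ii) the NJ topology of the quartet
#' pairs the paralogs, and (iii) that topology holds in at least
#' `support_threshold` of `B` codon-column bootstrap replicates. The
#' acceptor is the copy with the larger ortholog Ks; when the two
#' ortholog Ks are elevated symmetrically (ratio within
#' `both_copies_ratio`) the direction is reported `both_copies`.
#'
#' @param quartet A filtered [GeneQuartet-class].
#' @param genome `"A"` (paralogs P1/P2) or `"B"` (S1/S2).
#' @param B Bootstrap replicates.
#' @param support_threshold Minimum topology bootstrap support.
#' @param both_copies_ratio Ortholog-Ks ratio under which both copies
#'   are reported affected.
#' @return One-row calls data.frame, or an empty one.
#' @export
detectWcv <- function(quartet, genome = "A", B = 1000,
                      support_threshold = 0.95, both_copies_ratio = 1.2) {
  ps <- pairStats(quartet)
  key <- paste(ps$gene_a, ps$gene_b, sep = ":")
  ksof <- function(a, b) ps$ks[match(paste(a, b, sep = ":"), key)]
  copies <- if (genome == "A") c("P1", "P2") else c("S1", "S2")
  ks_pp <- if (genome == "A") ksof("P1", "P2") else ksof("S1", "S2")
  ks_o1 <- ksof("P1", "S1")
  ks_o2 <- ksof("P2", "S2")
  if (any(!is.finite(c(ks_pp, ks_o1, ks_o2)))) return(.emptyCalls())
  if (!(ks_pp < min(ks_o1, ks_o2))) return(.emptyCalls())
  if (quartetTopology(quartet) != "paralogs_sister") return(.emptyCalls())
  support <- topologyBootstrapSupport(quartet, B = B)
  if (support < support_threshold) return(.emptyCalls())
  orth <- c(ks_o1, ks_o2)
  acc_i <- which.max(orth)
  ratio <- max(orth) / max(min(orth), 1e-12)
  conf <- if (ratio <= both_copies_ratio) "both_copies" else "resolved"
  acceptor <- copies[acc_i]; donor <- copies[3 - acc_i]
  glen <- max(columnMaps(quartet)[[acceptor]], na.rm = TRUE)
  data.frame(
    quartet_id = quartetId(quartet), type = "WCV",
    converted_genome = genome,
    acceptor = quartetGenes(quartet)[[acceptor]],
    donor = quartetGenes(quartet)[[donor]],
    tract_start = 1L, tract_end = glen,
    aln_start = 1L,
    aln_end = length(columnMaps(quartet)[[acceptor]]),
    score = NA_real_, p_value = 1 - support,
    direction_confidence = conf, stringsAsFactors = FALSE)
}

#' Classify a quartet's conversion status per genome
#'
#' WCV takes precedence over PCV for the same paralog pair.
#'
#' @param calls data.frame of conversion calls for one quartet (from
#'   both detectors, both genomes).
#' @param quartet_id Identifier used when `calls` is empty.
#' @return data.frame `quartet_id`, `genome`, `status` with one row per
#'   genome (`"A"`, `"B"`), status in `nonconverted`, `WCV`, `PCV`.
#' @export
classifyQuartet <- function(calls, quartet_id = unique(calls$quartet_id)) {
  if (length(quartet_id) == 0) quartet_id <- NA_character_
  status <- vapply(c("A", "B"), function(g) {
    sub <- calls[calls$converted_genome == g, , drop = FALSE]
    if (nrow(sub) == 0) "nonconverted"
    else if (any(sub$type == "WCV")) "WCV"
    else "PCV"
  }, character(1))
  data.frame(quartet_id = quartet_id[1], genome = c("A", "B"),
             status = unname(status), stringsAsFactors = FALSE)
}

#' Run both conversion detectors on a list of quartets
#'
#' Applies the reliability filter, then [detectWcv()] and [detectPcv()]
#' on both genomes of every passing quartet.
#'
#' @param quartets List of [GeneQuartet-class] objects.
#' @param config A [pipelineConfig()].
#' @return List with `calls` (row-bound call table), `status` (one row
#'   per quartet and genome) and `filtered` (per-quartet keep/reason).
#' @export
scanQuartets <- function(quartets, config = pipelineConfig()) {
  calls <- list(); status <- list(); filt <- list()
  for (q in quartets) {
    fl <- filterQuartet(q)
    filt[[length(filt) + 1]] <- data.frame(
      quartet_id = quartetId(q), keep = fl$keep, reason = fl$reason,
      stringsAsFactors = FALSE)
    if (!fl$keep) next
    qc <- .emptyCalls()
    for (g in c("A", "B")) {
      w <- detectWcv(q, genome = g, B = config$bootstrap_B)
      p <- detectPcv(q, genome = g, min_tract_len = config$min_tract_len,
                     alpha = config$alpha, B = config$bootstrap_B)
      qc <- rbind(qc, w, p)
    }
    calls[[length(calls) + 1]] <- qc
    status[[length(status) + 1]] <- classifyQuartet(qc, quartetId(q))
  }
  list(calls = if (length(calls)) do.call(rbind, calls) else .emptyCalls(),
       status = if (length(status)) do.call(rbind, status) else
         data.frame(quartet_id = character(0), genome = character(0),
                    status = character(0)),
       filtered = do.call(rbind, filt))
}
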