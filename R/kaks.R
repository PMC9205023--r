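# Nei-Gojobori (1986) evolutionary distances on protein-guided codon
# alignments, with Jukes-Cantor multiple-hit correction.

BASES <- c("A", "C", "G", "T")

.permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(.permutations(v[-i]), function(p) c(v[i], p))))
}

# Codon index convention: idx = 16*b1 + 4*b2 + b3 with A,C,G,T = 0..3
# (0-based; R tables are indexed idx+1). Shared with the C++ simulator.
.codonTables <- function() {
  if (!is.null(.qc_cache$codon)) return(.qc_cache$codon)
  grid <- expand.grid(b3 = 0:3, b2 = 0:3, b1 = 0:3)
  codons <- paste0(BASES[grid$b1 + 1], BASES[grid$b2 + 1], BASES[grid$b3 + 1])
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  is_stop <- aa == "*"
  place <- c(16L, 4L, 1L)

  # NG86 synonymous site counts: at each codon position, the fraction of
  # the three possible changes that are synonymous; changes to stop
  # codons count as nonsynonymous-but-unobservable (denominator stays 3).
  syn_sites <- rep(NA_real_, 64)
  for (i in which(!is_stop)) {
    s <- 0
    for (pos in 1:3) {
      base <- ((i - 1) %/% place[pos]) %% 4
      for (nb in setdiff(0:3, base)) {
        j <- i + (nb - base) * place[pos]
        if (!is_stop[j] && aa[j] == aa[i]) s <- s + 1 / 3
      }
    }
    syn_sites[i] <- s
  }

  # Observed differences per codon pair, averaged over minimal mutation
  # pathways; pathways passing through a stop codon are excluded unless
  # every pathway does.
  nd <- sd_ <- matrix(NA_real_, 64, 64)
  ch <- strsplit(codons, "")
  for (i in which(!is_stop)) {
    for (j in which(!is_stop)) {
      dpos <- which(ch[[i]] != ch[[j]])
      if (length(dpos) == 0) { nd[i, j] <- 0; sd_[i, j] <- 0; next }
      paths <- .permutations(dpos)
      res <- lapply(paths, function(ord) {
        cur <- i; syn <- 0; non <- 0; blocked <- FALSE
        for (pos in ord) {
          from <- ((cur - 1) %/% place[pos]) %% 4
          to <- match(ch[[j]][pos], BASES) - 1
          nxt <- cur + (to - from) * place[pos]
          if (is_stop[nxt]) blocked <- TRUE
          if (aa[nxt] == aa[cur]) syn <- syn + 1 else non <- non + 1
          cur <- nxt
        }
        c(syn, non, blocked)
      })
      res <- do.call(rbind, res)
      use <- if (any(res[, 3] == 0)) res[res[, 3] == 0, , drop = FALSE] else res
      sd_[i, j] <- mean(use[, 1])
      nd[i, j] <- mean(use[, 2])
    }
  }
  .qc_cache$codon <- list(codons = codons, aa = aa, is_stop = is_stop,
                          syn_sites = syn_sites, nd = nd, sd = sd_)
  .qc_cache$codon
}

# Aligned nucleotide character vector -> 1-based codon indices (NA where
# any base of the codon is a gap, N or other ambiguity).
.codonIdx <- function(chars) {
  b <- match(chars, BASES) - 1L
  n <- length(b) %/% 3L
  idx <- 16L * b[seq(1, by = 3, length.out = n)] +
    4L * b[seq(2, by = 3, length.out = n)] +
    b[seq(3, by = 3, length.out = n)] + 1L
  idx
}

#' Jukes-Cantor correction of a raw difference proportion
#'
#' Converts a raw proportion of differing sites `p` into an estimated
#' number of substitutions per site, `d = -(3/4) * log(1 - 4p/3)`,
#' accounting for multiple hits at the same site. Proportions at or
#' beyond the model's saturation point (`p >= 0.75`) return `NA`.
#'
#' @param p Numeric vector of raw difference proportions in `[0, 0.75)`.
#' @return Numeric vector of corrected distances; `NA` where saturated.
#' @examples
#' jcCorrect(c(0, 0.03, 0.2))
#' @export
jcCorrect <- function(p) {
  if (any(p < 0, na.rm = TRUE)) stop("proportions must be non-negative")
  d <- ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
  d
}

#' Construct a CodonAlignment from pre-aligned sequences
#'
#' @param seqs Named character vector or DNAStringSet of equal-length
#'   aligned, in-frame sequences (gap character `-`, whole codons only).
#' @return A [CodonAlignment-class].
#' @export
codonAlignment <- function(seqs) {
  aln <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(aln))) names(aln) <- paste0("seq", seq_along(aln))
  chars <- strsplit(as.character(aln), "")
  maps <- lapply(chars, function(ch) {
    m <- rep(NA_integer_, length(ch))
    ung <- ch != "-"
    m[ung] <- seq_len(sum(ung))
    m
  })
  methods::new("CodonAlignment", aln = aln, maps = maps)
}

.translateCds <- function(cds, id) {
  tab <- .codonTables()
  chars <- strsplit(cds, "")[[1]]
  if (length(chars) %% 3 != 0)
    stop("CDS length of ", id, " not divisible by 3")
  idx <- .codonIdx(chars)
  aa <- ifelse(is.na(idx), "X", tab$aa[idx])
  # a terminal stop codon is tolerated and trimmed; internal stops are
  # fatal because NG86 site counting is undefined for them
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*", na.rm = TRUE))
    stop("internal stop codon in CDS of ", id)
  aa
}

#' Protein-guided global pairwise codon alignment
#'
#' Translates two CDSs, aligns the translations globally
#' (Needleman-Wunsch, BLOSUM62, affine gap penalties: open 10,
#' extend 0.5) and back-translates the protein alignment to codons, so
#' gaps always occur in whole-codon units. A terminal stop codon is
#' trimmed before alignment; internal stop codons are an error.
#'
#' @param cds_a,cds_b CDS nucleotide strings (length divisible by 3).
#' @param ids Character vector of length 2 naming the sequences.
#' @return A two-sequence [CodonAlignment-class].
#' @export
alignPair <- function(cds_a, cds_b, ids = c("seq_a", "seq_b")) {
  cds_a <- as.character(cds_a); cds_b <- as.character(cds_b)
  aa_a <- .translateCds(cds_a, ids[1])
  aa_b <- .translateCds(cds_b, ids[2])
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(aa_a, collapse = "")),
    Biostrings::AAString(paste(aa_b, collapse = "")),
    substitutionMatrix = .blosum62(), gapOpening = 10, gapExtension = 0.5,
    type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  back <- function(aachars, cds, n_aa) {
    codons <- substring(cds, seq(1, by = 3, length.out = n_aa),
                        seq(3, by = 3, length.out = n_aa))
    out <- character(length(aachars))
    k <- 0
    for (i in seq_along(aachars)) {
      if (aachars[i] == "-") out[i] <- "---"
      else { k <- k + 1; out[i] <- codons[k] }
    }
    paste(out, collapse = "")
  }
  seqs <- c(back(pat, cds_a, length(aa_a)), back(sub, cds_b, length(aa_b)))
  names(seqs) <- ids
  codonAlignment(seqs)
}

.blosum62 <- function() {
  if (is.null(.qc_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .qc_cache$blosum62 <- e$BLOSUM62
  }
  .qc_cache$blosum62
}

#' Alignment score of a protein-guided pairwise alignment
#'
#' Convenience wrapper returning the Needleman-Wunsch score that
#' [alignPair()] optimizes, for checking against independent aligners.
#'
#' @inheritParams alignPair
#' @return Numeric alignment score.
#' @export
alignPairScore <- function(cds_a, cds_b, ids = c("seq_a", "seq_b")) {
  aa_a <- .translateCds(as.character(cds_a), ids[1])
  aa_b <- .translateCds(as.character(cds_b), ids[2])
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(aa_a, collapse = "")),
    Biostrings::AAString(paste(aa_b, collapse = "")),
    substitutionMatrix = .blosum62(), gapOpening = 10, gapExtension = 0.5,
    type = "global")
  Biostrings::score(pa)
}

# Codon index vectors for two genes of an alignment, plus the logical
# mask of codon columns comparable for the pair (no gap, no ambiguity).
.pairCodons <- function(aln, a, b) {
  seqs <- as.character(alignedSeqs(aln))
  if (!all(c(a, b) %in% names(seqs))) stop("genes not in alignment")
  ia <- .codonIdx(strsplit(seqs[[a]], "")[[1]])
  ib <- .codonIdx(strsplit(seqs[[b]], "")[[1]])
  list(ia = ia, ib = ib, ok = !is.na(ia) & !is.na(ib))
}

#' Nei-Gojobori (1986) pairwise substitution statistics
#'
#' Computes NG86 synonymous/nonsynonymous site counts (fractional
#' convention, averaged over the two sequences), observed differences
#' (averaged over all minimal substitution pathways, stop-containing
#' pathways excluded), and Jukes-Cantor-corrected distances. The
#' JC-corrected values are reported both as `ka`/`ks` and, mirroring the
#' output schema of the wider pipeline, as `pn`/`ps`. Codon columns with
#' a gap or ambiguous base in either gene are ignored for the pair.
#' Raw proportions at or above 0.745 are flagged saturated and the
#' corresponding distance is reported missing.
#'
#' @param aln A [CodonAlignment-class].
#' @param genes Character vector of length 2; defaults to the first two
#'   sequences of the alignment.
#' @return One-row data.frame: `gene_a`, `gene_b`, `ka`, `ks`, `pn`,
#'   `ps`, `n_sites`, `s_sites`, `nd`, `sd`, `aa_identity`,
#'   `gap_fraction`, `saturated`, `n_codons`.
#' @export
ng86 <- function(aln, genes = names(alignedSeqs(aln))[1:2]) {
  tab <- .codonTables()
  pc <- .pairCodons(aln, genes[1], genes[2])
  ok <- pc$ok
  L <- sum(ok)
  if (L < 1) stop("no ungapped codon column shared by ", genes[1], " and ",
                  genes[2])
  ia <- pc$ia[ok]; ib <- pc$ib[ok]
  s_sites <- sum((tab$syn_sites[ia] + tab$syn_sites[ib]) / 2)
  n_sites <- 3 * L - s_sites
  sd_obs <- sum(tab$sd[cbind(ia, ib)])
  nd_obs <- sum(tab$nd[cbind(ia, ib)])
  ps_raw <- if (s_sites > 0) sd_obs / s_sites else NA_real_
  pn_raw <- if (n_sites > 0) nd_obs / n_sites else NA_real_
  sat_s <- !is.na(ps_raw) && ps_raw >= 0.745
  sat_n <- !is.na(pn_raw) && pn_raw >= 0.745
  ks <- if (is.na(ps_raw) || sat_s) NA_real_ else jcCorrect(ps_raw)
  ka <- if (is.na(pn_raw) || sat_n) NA_real_ else jcCorrect(pn_raw)
  idg <- aaIdentityGaps(aln, genes)
  data.frame(gene_a = genes[1], gene_b = genes[2], ka = ka, ks = ks,
             pn = ka, ps = ks, n_sites = n_sites, s_sites = s_sites,
             nd = nd_obs, sd = sd_obs, aa_identity = idg$aa_identity,
             gap_fraction = idg$gap_fraction, saturated = sat_s || sat_n,
             n_codons = L, stringsAsFactors = FALSE)
}

#' Amino-acid identity and gap fraction of an aligned gene pair
#'
#' Identity is computed over codon columns where both genes carry an
#' unambiguous codon; the gap fraction is the fraction of all codon
#' columns containing a gap in either gene.
#'
#' @inheritParams ng86
#' @return List with `aa_identity` (NA when no comparable column) and
#'   `gap_fraction`.
#' @export
aaIdentityGaps <- function(aln, genes = names(alignedSeqs(aln))[1:2]) {
  tab <- .codonTables()
  seqs <- as.character(alignedSeqs(aln))
  cha <- strsplit(seqs[[genes[1]]], "")[[1]]
  chb <- strsplit(seqs[[genes[2]]], "")[[1]]
  ia <- .codonIdx(cha); ib <- .codonIdx(chb)
  gap_a <- cha[seq(1, by = 3, length.out = length(ia))] == "-"
  gap_b <- chb[seq(1, by = 3, length.out = length(ib))] == "-"
  gap_fraction <- mean(gap_a | gap_b)
  ok <- !is.na(ia) & !is.na(ib)
  aa_identity <- if (sum(ok) == 0) NA_real_ else
    mean(tab$aa[ia[ok]] == tab$aa[ib[ok]])
  list(aa_identity = aa_identity, gap_fraction = gap_fraction)
}

# Anchor-based four-way codon alignment: partners are pairwise-aligned
# to P1 and merged on P1 codon coordinates; partner codons inserted
# relative to P1 are stacked left-aligned in shared insertion slots.
#' Four-way codon alignment of a quartet
#'
#' Aligns S1, P2 and S2 to P1 with [alignPair()] and merges the three
#' pairwise alignments on P1's codon coordinates into one alignment in
#' which all six gene pairs share columns.
#'
#' @param cds Named character vector or DNAStringSet with elements
#'   `P1`, `P2`, `S1`, `S2`.
#' @return A four-sequence [CodonAlignment-class] (order P1, P2, S1, S2).
#' @export
quartetAlign <- function(cds) {
  cds <- setNames(as.character(Biostrings::DNAStringSet(cds)), names(cds))
  stopifnot(all(c("P1", "P2", "S1", "S2") %in% names(cds)))
  partners <- c("S1", "P2", "S2")
  n1 <- NULL
  per <- list()
  for (p in partners) {
    pw <- alignPair(cds[["P1"]], cds[[p]], ids = c("P1", p))
    seqs <- as.character(alignedSeqs(pw))
    c1 <- strsplit(seqs[["P1"]], "")[[1]]
    c2 <- strsplit(seqs[[p]], "")[[1]]
    ncol <- length(c1) %/% 3
    cod1 <- substring(seqs[["P1"]], 3 * seq_len(ncol) - 2, 3 * seq_len(ncol))
    cod2 <- substring(seqs[[p]], 3 * seq_len(ncol) - 2, 3 * seq_len(ncol))
    anchor_pos <- cumsum(cod1 != "---")  # P1 codon index at each column
    matched <- rep("---", max(anchor_pos))
    m <- cod1 != "---"
    matched[anchor_pos[m]] <- cod2[m]
    ins <- split(cod2[!m], anchor_pos[!m])  # keyed by preceding P1 codon
    if (is.null(n1)) n1 <- max(anchor_pos)
    per[[p]] <- list(matched = matched, ins = ins)
  }
  ins_len <- integer(n1 + 1)  # slot g = insertions after P1 codon g
  for (p in partners) {
    il <- per[[p]]$ins
    for (g in names(il))
      ins_len[as.integer(g) + 1] <- max(ins_len[as.integer(g) + 1],
                                        length(il[[g]]))
  }
  build_row <- function(matched, ins) {
    out <- character(0)
    for (g in 0:n1) {
      blk <- rep("---", ins_len[g + 1])
      got <- ins[[as.character(g)]]
      if (!is.null(got)) blk[seq_along(got)] <- got
      out <- c(out, blk, if (g < n1) matched[g + 1])
    }
    paste(out, collapse = "")
  }
  p1cod <- substring(cds[["P1"]], 3 * seq_len(n1) - 2, 3 * seq_len(n1))
  rows <- c(P1 = build_row(p1cod, list()),
            P2 = build_row(per$P2$matched, per$P2$ins),
            S1 = build_row(per$S1$matched, per$S1$ins),
            S2 = build_row(per$S2$matched, per$S2$ins))
  codonAlignment(rows)
}
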