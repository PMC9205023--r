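# Independent reference implementations used as oracles. Each is a
# deliberately naive second route to the quantity under test and shares
# no code with the package internals.

# --- NG86 by direct recursive pathway enumeration ---------------------

.o_code <- local({
  b <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  codons <- sort(codons)  # independent ordering from the package's
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  list(codons = codons, aa = setNames(aa, codons))
})

oracle_syn_sites <- function(codon) {
  b <- c("A", "C", "G", "T")
  aa <- .o_code$aa
  s <- 0
  for (pos in 1:3) {
    for (nb in setdiff(b, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nb
      if (aa[[alt]] != "*" && aa[[alt]] == aa[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

# average syn/nonsyn differences over minimal pathways; pathways through
# stop codons excluded unless all are blocked
oracle_pair_diffs <- function(c1, c2) {
  aa <- .o_code$aa
  dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(dpos) == 0) return(c(syn = 0, non = 0))
  orderings <- if (length(dpos) == 1) list(dpos) else {
    prm <- list()
    rec <- function(prefix, rest) {
      if (!length(rest)) { prm[[length(prm) + 1]] <<- prefix; return() }
      for (k in seq_along(rest)) rec(c(prefix, rest[k]), rest[-k])
    }
    rec(integer(0), dpos)
    prm
  }
  walk <- function(ord) {
    cur <- c1; syn <- 0; non <- 0; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (aa[[nxt]] == "*") blocked <- TRUE
      if (aa[[nxt]] == aa[[cur]]) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    c(syn, non, blocked)
  }
  res <- t(vapply(orderings, walk, numeric(3)))
  use <- if (any(res[, 3] == 0)) res[res[, 3] == 0, , drop = FALSE] else res
  c(syn = mean(use[, 1]), non = mean(use[, 2]))
}

oracle_ng86 <- function(cds1, cds2) {
  n <- nchar(cds1) / 3
  S <- N <- Sd <- Nd <- 0
  for (i in seq_len(n)) {
    c1 <- substr(cds1, 3 * i - 2, 3 * i)
    c2 <- substr(cds2, 3 * i - 2, 3 * i)
    S <- S + (oracle_syn_sites(c1) + oracle_syn_sites(c2)) / 2
    d <- oracle_pair_diffs(c1, c2)
    Sd <- Sd + d[["syn"]]
    Nd <- Nd + d[["non"]]
  }
  N <- 3 * n - S
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(s_sites = S, n_sites = N, sd = Sd, nd = Nd,
       ks = jc(Sd / S), ka = jc(Nd / N))
}

# --- Ruzzo-Tompa by the formal definition -----------------------------
# A segment [i, j] is maximal-scoring iff its total is positive, every
# proper prefix and suffix sum is strictly positive, and it is not
# contained in another segment with the same properties.

oracle_rt <- function(scores) {
  n <- length(scores)
  cand <- list()
  for (i in seq_len(n)) for (j in i:n) {
    seg <- scores[i:j]
    tot <- sum(seg)
    if (tot <= 0) next
    k <- length(seg)
    pre <- cumsum(seg)
    suf <- rev(cumsum(rev(seg)))
    if (k > 1 && (any(pre[1:(k - 1)] <= 0) || any(suf[2:k] <= 0))) next
    cand[[length(cand) + 1]] <- c(i, j, tot)
  }
  if (!length(cand)) return(matrix(numeric(0), 0, 3))
  m <- do.call(rbind, cand)
  keep <- vapply(seq_len(nrow(m)), function(r) {
    !any(m[, 1] <= m[r, 1] & m[, 2] >= m[r, 2] &
           (m[, 1] < m[r, 1] | m[, 2] > m[r, 2]))
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  m[order(m[, 1]), , drop = FALSE]
}

# --- four-taxon topology by exhaustive least-squares ------------------
# fits the five branch lengths of each of the three unrooted topologies
# by ordinary least squares and returns the best-fitting grouping.

oracle_quartet_ls <- function(d) {
  # d: named vector with P1:P2, S1:S2, P1:S1, P2:S2, P1:S2, P2:S1
  taxa <- c("P1", "P2", "S1", "S2")
  pairs <- combn(taxa, 2)
  obs <- apply(pairs, 2, function(p) {
    nm1 <- paste(p, collapse = ":"); nm2 <- paste(rev(p), collapse = ":")
    if (nm1 %in% names(d)) d[[nm1]] else d[[nm2]]
  })
  fitss <- function(cherry) {
    # design matrix: columns e1..e4 (tip branches), m (internal)
    X <- matrix(0, 6, 5)
    for (k in 1:6) {
      p <- pairs[, k]
      X[k, match(p, taxa)] <- 1
      same_side <- all(p %in% cherry) || all(!p %in% cherry)
      if (!same_side) X[k, 5] <- 1
    }
    fit <- lm.fit(X, obs)
    sum(fit$residuals^2)
  }
  ss <- c(expected = fitss(c("P1", "S1")),
          paralogs_sister = fitss(c("P1", "P2")),
          mixed = fitss(c("P1", "S2")))
  names(which.min(ss))
}

# --- textbook closed forms --------------------------------------------

oracle_pearson_r <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

oracle_pooled_t <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# --- affine-gap global alignment score (Gotoh) ------------------------
# end gaps penalized; gap of length L costs open + L * extend, matching
# the alignPair() convention.

oracle_gotoh_score <- function(aa1, aa2, submat, open = 10, extend = 0.5) {
  n <- length(aa1); m <- length(aa2)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in match
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap in seq2 (deletion)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap in seq1 (insertion)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + extend * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + extend * j)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- submat[aa1[i], aa2[j]]
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                           X[i, j + 1] - extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                           Y[i + 1, j] - extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# exhaustive global-alignment enumeration for very short sequences,
# used to validate the Gotoh oracle itself
oracle_enum_score <- function(aa1, aa2, submat, open = 10, extend = 0.5) {
  best <- -Inf
  rec <- function(i, j, prev, score) {
    if (i > length(aa1) && j > length(aa2)) {
      best <<- max(best, score); return()
    }
    if (i <= length(aa1) && j <= length(aa2))
      rec(i + 1, j + 1, "M", score + submat[aa1[i], aa2[j]])
    if (i <= length(aa1))
      rec(i + 1, j, "X",
          score - (if (prev == "X") extend else open + extend))
    if (j <= length(aa2))
      rec(i, j + 1, "Y",
          score - (if (prev == "Y") extend else open + extend))
  }
  rec(1, 1, "none", 0)
  best
}

# --- exhaustive gap-constrained monotone chain search -----------------
# longest chain with strictly increasing x, strictly monotone y (either
# direction) and successive gaps <= max_gap on both axes; returns the
# indices of one best chain, ties broken by the smaller starting x then y.

oracle_best_chain <- function(x, y, max_gap) {
  n <- length(x)
  best <- integer(0)
  better <- function(a, b) {
    if (length(a) != length(b)) return(length(a) > length(b))
    if (!length(a)) return(FALSE)
    if (x[a[1]] != x[b[1]]) return(x[a[1]] < x[b[1]])
    y[a[1]] < y[b[1]]
  }
  for (dir in c(1, -1)) {
    yy <- dir * y
    rec <- function(chain, last) {
      if (better(chain, best)) best <<- chain
      for (k in seq_len(n)) {
        if (length(chain) && (x[k] <= x[last] || yy[k] <= yy[last] ||
                              x[k] - x[last] > max_gap ||
                              abs(y[k] - y[last]) > max_gap)) next
        if (!length(chain) || (x[k] > x[last] && yy[k] > yy[last]))
          rec(c(chain, k), k)
      }
    }
    rec(integer(0), NA)
  }
  best
}

# --- misc helpers -----------------------------------------------------

random_cds <- function(n_codons) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), 3 * n_codons, TRUE),
               collapse = "")
    aa <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(s))), "")[[1]]
    if (!any(aa == "*")) return(s)
  }
}

# quartet whose alignment is taken directly from the (gap-free)
# simulated sequences and whose pair statistics are skipped; enough for
# the PCV scan, which only needs the alignment
make_scan_quartet <- function(sim, id = "q1") {
  aln <- codonAlignment(as.character(sim$seqs))
  methods::new("GeneQuartet", id = id,
               genes = c(P1 = "P1", P2 = "P2", S1 = "S1", S2 = "S2"),
               alignment = aln, pairStats = data.frame(),
               paralogSide = "A", provenance = character(0))
}

make_quartet <- function(sim, id = "q1") {
  aln <- quartetAlign(as.character(sim$seqs))
  ps <- do.call(rbind, lapply(
    list(c("P1", "P2"), c("S1", "S2"), c("P1", "S1"), c("P2", "S2"),
         c("P1", "S2"), c("P2", "S1")),
    function(p) ng86(aln, p)))
  methods::new("GeneQuartet", id = id,
               genes = c(P1 = "P1", P2 = "P2", S1 = "S1", S2 = "S2"),
               alignment = aln, pairStats = ps, paralogSide = "A",
               provenance = character(0))
}

binom_ci <- function(p, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  c(p - z * sqrt(p * (1 - p) / n), p + z * sqrt(p * (1 - p) / n))
}
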