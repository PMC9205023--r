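# Codon-level simulator of homologous gene quartets, genome pairs and
# expression tables, with full ground truth. The quartet topology is
# ((P1,S1),(P2,S2)) rooted at the WGD; each branch evolves under a
# Jukes-Cantor-style codon process in which proposals to stop codons are
# rejected, synonymous proposals always fix and nonsynonymous proposals
# fix with relative probability ka_ks_ratio, so a branch of length d
# accumulates d expected synonymous substitutions per NG86 synonymous
# site.

.jc_p <- function(d) 0.75 * (1 - exp(-4 * d / 3))

#' Configuration of a simulated quartet
#'
#' @param n_codons Number of codons of the ancestral gene.
#' @param k_par Expected synonymous divergence (Ks) of the paralog pair
#'   absent conversion; the WGD age in Ks units.
#' @param k_orth Expected Ks of each ortholog pair; the speciation age.
#' @param ka_ks_ratio Nonsynonymous/synonymous rate ratio.
#' @param conversion One conversion event, or an (possibly empty) list
#'   of events. Each event is `list(type = "none")`, `list(type =
#'   "whole", acceptor, donor, time_fraction)` or `list(type = "tract",
#'   start_nt, end_nt, acceptor, donor, time_fraction)`. Tract bounds
#'   are 1-based inclusive ungapped nucleotide coordinates;
#'   `acceptor`/`donor` must be a paralog pair (`P1`/`P2` or
#'   `S1`/`S2`); `time_fraction` runs from 0 (at speciation) to 1 (at
#'   present). The two genomes' pairs may each carry an event.
#' @return A validated list of class `QuartetSimConfig`; `conversion`
#'   is normalized to a list of events.
#' @export
quartetSimConfig <- function(n_codons = 500, k_par = 0.25, k_orth = 0.12,
                             ka_ks_ratio = 0.3,
                             conversion = list(type = "none")) {
  if (k_orth < 0 || k_par < k_orth)
    stop("need 0 <= k_orth <= k_par")
  if (.jc_p(k_par) > 0.74)
    stop("k_par implies raw divergence > 0.74 (Jukes-Cantor saturation)")
  if (ka_ks_ratio < 0) stop("ka_ks_ratio must be non-negative")
  if (!is.null(conversion$type)) conversion <- list(conversion)
  events <- list()
  for (ev in conversion) {
    type <- match.arg(ev$type, c("none", "whole", "tract"))
    if (type == "none") next
    pair <- sort(c(ev$acceptor, ev$donor))
    if (!identical(pair, c("P1", "P2")) && !identical(pair, c("S1", "S2")))
      stop("acceptor/donor must be a paralog pair (P1/P2 or S1/S2)")
    tf <- ev$time_fraction
    if (is.null(tf) || tf < 0 || tf > 1)
      stop("time_fraction must lie in [0, 1]")
    if (type == "tract") {
      if (ev$start_nt < 1 || ev$end_nt > 3 * n_codons ||
          ev$start_nt > ev$end_nt)
        stop("tract bounds outside the gene")
    }
    events[[length(events) + 1]] <- ev
  }
  structure(list(n_codons = n_codons, k_par = k_par, k_orth = k_orth,
                 ka_ks_ratio = ka_ks_ratio, conversion = events),
            class = "QuartetSimConfig")
}

# 0-based codon vector helpers shared with the C++ evolution kernel
.simTables <- function() {
  tab <- .codonTables()
  list(aa = match(tab$aa, unique(tab$aa)), is_stop = tab$is_stop,
       codons = tab$codons)
}

.randomCodingSeq <- function(n_codons) {
  tab <- .codonTables()
  sample(which(!tab$is_stop), n_codons, replace = TRUE) - 1L
}

.evolve <- function(codons0, d, omega) {
  if (d <= 0) return(codons0)
  st <- .simTables()
  .evolve_codons_cpp(codons0, d, omega, st$aa, st$is_stop)
}

.codonsToString <- function(codons0) {
  paste(.codonTables()$codons[codons0 + 1L], collapse = "")
}

# Overwrite the acceptor's tract with the donor's tract. Chimeric codons
# at tract edges that would create a stop are completed from the donor.
.implantTract <- function(acceptor, donor, start_nt, end_nt) {
  tab <- .codonTables()
  a <- strsplit(.codonsToString(acceptor), "")[[1]]
  d <- strsplit(.codonsToString(donor), "")[[1]]
  a[start_nt:end_nt] <- d[start_nt:end_nt]
  out <- .codonIdx(a) - 1L
  bad <- which(tab$is_stop[out + 1L])
  if (length(bad)) out[bad] <- donor[bad]
  out
}

#' Simulate one homologous gene quartet
#'
#' Draws a stop-codon-free ancestral gene, duplicates it at the WGD,
#' evolves the two paralogous lineages for `(k_par - k_orth)/2`
#' synonymous substitutions per site each, splits each lineage at
#' speciation and evolves the four tips for `k_orth/2` each, so the
#' expected NG86 Ks is `k_par` for the paralog pairs and `k_orth` for
#' the ortholog pairs. Each configured conversion event overwrites the
#' acceptor's tract with the donor's at the configured time point of the
#' post-speciation period, after which both copies continue evolving
#' independently; events are applied in order of their time fractions.
#'
#' @param cfg A [quartetSimConfig()].
#' @param seed Optional integer seed.
#' @param id Quartet identifier recorded in the truth table.
#' @return List with `seqs` (DNAStringSet P1, P2, S1, S2) and `truth`
#'   (data.frame of implanted events: `quartet_id`, `type`, `acceptor`,
#'   `donor`, `tract_start`, `tract_end`, `time_fraction`; zero rows if
#'   none).
#' @export
simulateQuartet <- function(cfg = quartetSimConfig(), seed = NULL,
                            id = "q1") {
  if (!inherits(cfg, "QuartetSimConfig")) stop("cfg must be a QuartetSimConfig")
  if (!is.null(seed)) set.seed(seed)
  omega <- cfg$ka_ks_ratio
  a_len <- (cfg$k_par - cfg$k_orth) / 2  # WGD -> speciation, per lineage
  b_len <- cfg$k_orth / 2                # speciation -> present, per branch
  anc <- .randomCodingSeq(cfg$n_codons)
  lin1 <- .evolve(anc, a_len, omega)
  lin2 <- .evolve(anc, a_len, omega)
  events <- cfg$conversion
  if (length(events) > 1)
    events <- events[order(vapply(events, `[[`, numeric(1),
                                  "time_fraction"))]
  tips <- list(P1 = lin1, S1 = lin1, P2 = lin2, S2 = lin2)
  truth <- data.frame(quartet_id = character(0), type = character(0),
                      acceptor = character(0), donor = character(0),
                      tract_start = integer(0), tract_end = integer(0),
                      time_fraction = numeric(0), stringsAsFactors = FALSE)
  t_now <- 0
  for (ev in events) {
    step <- (ev$time_fraction - t_now) * b_len
    if (step > 0) tips <- lapply(tips, .evolve, d = step, omega = omega)
    t_now <- ev$time_fraction
    bounds <- if (ev$type == "whole") c(1L, 3L * cfg$n_codons) else
      c(as.integer(ev$start_nt), as.integer(ev$end_nt))
    tips[[ev$acceptor]] <- .implantTract(tips[[ev$acceptor]],
                                         tips[[ev$donor]],
                                         bounds[1], bounds[2])
    truth <- rbind(truth, data.frame(
      quartet_id = id,
      type = if (ev$type == "whole") "WCV" else "PCV",
      acceptor = ev$acceptor, donor = ev$donor,
      tract_start = bounds[1], tract_end = bounds[2],
      time_fraction = ev$time_fraction, stringsAsFactors = FALSE))
  }
  rest <- (1 - t_now) * b_len
  if (rest > 0) tips <- lapply(tips, .evolve, d = rest, omega = omega)
  seqs <- Biostrings::DNAStringSet(vapply(tips[c("P1", "P2", "S1", "S2")],
                                          .codonsToString, character(1)))
  list(seqs = seqs, truth = truth)
}

#' Simulate a set of quartets with mixed conversion status
#'
#' Event types are assigned by the given fractions (`round(n * frac)`
#' quartets each); PCV tract lengths are drawn uniformly from
#' `tract_len_range` and placed uniformly within the gene; the acceptor
#' copy and the affected genome are drawn uniformly.
#'
#' @param n Number of quartets.
#' @param pcv_fraction,wcv_fraction Fractions of quartets receiving a
#'   partial or whole conversion event (`pcv_fraction + wcv_fraction <= 1`).
#' @param cfg Template [quartetSimConfig()]; its `conversion` field is
#'   overridden per quartet.
#' @param tract_len_range Range (nt) of PCV tract lengths.
#' @param time_fraction Time point of the implanted events.
#' @param genomes Which genome's paralog pair may be converted
#'   (`"P"`, `"S"`, or `c("P","S")` for a uniform draw).
#' @param seed Optional integer seed.
#' @return List with `quartets` (list of [simulateQuartet()] results)
#'   and `truth` (row-bound truth table).
#' @export
simulateQuartetSet <- function(n, pcv_fraction = 0, wcv_fraction = 0,
                               cfg = quartetSimConfig(),
                               tract_len_range = c(30, 120),
                               time_fraction = 1, genomes = "P",
                               seed = NULL) {
  if (pcv_fraction + wcv_fraction > 1)
    stop("pcv_fraction + wcv_fraction must not exceed 1")
  if (!is.null(seed)) set.seed(seed)
  n_pcv <- round(n * pcv_fraction)
  n_wcv <- round(n * wcv_fraction)
  types <- sample(c(rep("tract", n_pcv), rep("whole", n_wcv),
                    rep("none", n - n_pcv - n_wcv)))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    conv <- list(type = types[i])
    if (types[i] != "none") {
      g <- if (length(genomes) > 1) sample(genomes, 1) else genomes
      copies <- if (g == "P") c("P1", "P2") else c("S1", "S2")
      acc <- sample(copies, 1)
      conv$acceptor <- acc
      conv$donor <- setdiff(copies, acc)
      conv$time_fraction <- time_fraction
      if (types[i] == "tract") {
        len <- min(sample(seq(tract_len_range[1], tract_len_range[2]), 1),
                   3 * cfg$n_codons)
        start <- sample(seq_len(3 * cfg$n_codons - len + 1), 1)
        conv$start_nt <- start
        conv$end_nt <- start + len - 1
      }
    }
    cfg_i <- quartetSimConfig(cfg$n_codons, cfg$k_par, cfg$k_orth,
                              cfg$ka_ks_ratio, conv)
    out[[i]] <- simulateQuartet(cfg_i, id = sprintf("q%04d", i))
  }
  truth <- do.call(rbind, lapply(out, `[[`, "truth"))
  list(quartets = out, truth = truth)
}

.placeholderCds <- function(n_codons) {
  substr(paste(rep("ATGGCTGCA", ceiling(n_codons / 3)), collapse = ""),
         1, 3 * n_codons)
}

.asProfileFun <- function(f) {
  if (is.function(f)) return(f)
  force(f); function(u) rep(f, length(u))
}

#' Simulate a duplicated genome pair with ground truth
#'
#' Builds two genomes (`A` and `B`). Chromosomes come in homoeologous
#' pairs (`1-2`, `3-4`, ...); each chromosome carries `genes_per_chrom`
#' genes at regular spacing. At each gene index of a chromosome pair, a
#' duplicate (SCT paralog) pair is present with probability
#' `duplicate_density(u)` (u = relative position along the chromosome);
#' remaining slots hold singleton genes. Genome B mirrors genome A's
#' layout, every gene having an ortholog at the same position, so clean
#' collinear diagonals exist within and between genomes. Each genome's
#' copy pair of a duplicate converts independently with probability
#' `converted_rate(u)`, split between whole-gene and tract events by
#' `wcv_fraction_of_converted`.
#'
#' @param n_chrom Even number of chromosomes per genome.
#' @param genes_per_chrom Genes per chromosome.
#' @param duplicate_density,converted_rate Constants in `[0, 1]` or
#'   functions of relative chromosome position returning values in
#'   `[0, 1]`.
#' @param n_codons,k_par,k_orth,ka_ks_ratio Passed to the quartet
#'   simulator.
#' @param wcv_fraction_of_converted Fraction of converted pairs that
#'   receive a whole-gene event (the rest receive tracts).
#' @param tract_len_range Range (nt) of PCV tract lengths.
#' @param wcv_time,pcv_time Time fractions of the implanted events.
#' @param bp_spacing Distance between successive gene starts (bp).
#' @param sequences When FALSE, skip sequence evolution and give every
#'   gene a fixed placeholder CDS; layout, pair and truth tables are
#'   unchanged. Useful for positional statistics at large gene counts.
#' @param seed Optional integer seed.
#' @return List: `catalogA`, `catalogB` ([GeneCatalog-class]), `pairs`
#'   (data.frame `gene_a`/`gene_b` of all homolog pairs: paralogs in A,
#'   paralogs in B, orthologs), `truth` (two rows per duplicate pair,
#'   one per genome: `pair_id`, genes, chromosomes, `genome`,
#'   `converted`, `type`, `acceptor`, `donor`, `tract_start`,
#'   `tract_end`) and `gene_truth` (per gene: `gene_id`, `genome`,
#'   `chromosome`, `midpoint`, `is_duplicate`, `converted` — converted
#'   flags mark acceptor genes).
#' @export
simulateGenomePair <- function(n_chrom = 4, genes_per_chrom = 100,
                               duplicate_density = 0.4,
                               converted_rate = 0.1,
                               n_codons = 200, k_par = 0.25, k_orth = 0.12,
                               ka_ks_ratio = 0.3,
                               wcv_fraction_of_converted = 0.5,
                               tract_len_range = c(30, 120),
                               wcv_time = 0.75, pcv_time = 1,
                               bp_spacing = 10000, sequences = TRUE,
                               seed = NULL) {
  if (n_chrom %% 2 != 0) stop("n_chrom must be even")
  if (!is.null(seed)) set.seed(seed)
  dens <- .asProfileFun(duplicate_density)
  conv <- .asProfileFun(converted_rate)
  u <- (seq_len(genes_per_chrom) - 0.5) / genes_per_chrom
  pd <- dens(u); pc <- conv(u)
  if (any(pd < 0 | pd > 1)) stop("duplicate_density outside [0, 1]")
  if (any(pc < 0 | pc > 1)) stop("converted_rate outside [0, 1]")

  gene_len <- 3 * n_codons
  rows <- list(); seqs <- list(); truth <- list(); gtruth <- list()
  pair_rows <- list()
  pid <- 0
  for (cp in seq_len(n_chrom / 2)) {
    c1 <- sprintf("chr%02d", 2 * cp - 1)
    c2 <- sprintf("chr%02d", 2 * cp)
    is_dup <- runif(genes_per_chrom) < pd
    for (j in seq_len(genes_per_chrom)) {
      start <- (j - 1) * bp_spacing + 1
      ids <- c(A1 = sprintf("A%s_g%04d", sub("chr", "c", c1), j),
               A2 = sprintf("A%s_g%04d", sub("chr", "c", c2), j),
               B1 = sprintf("B%s_g%04d", sub("chr", "c", c1), j),
               B2 = sprintf("B%s_g%04d", sub("chr", "c", c2), j))
      if (is_dup[j]) {
        pid <- pid + 1
        # each genome's copy pair converts independently
        ev_list <- list()
        for (g in c("A", "B")) {
          if (runif(1) >= pc[j]) next
          whole <- runif(1) < wcv_fraction_of_converted
          copies <- if (g == "A") c("P1", "P2") else c("S1", "S2")
          acc <- sample(copies, 1)
          ev <- list(type = if (whole) "whole" else "tract",
                     acceptor = acc, donor = setdiff(copies, acc),
                     time_fraction = if (whole) wcv_time else pcv_time)
          if (!whole) {
            len <- min(sample(seq(tract_len_range[1],
                                  tract_len_range[2]), 1), gene_len)
            st <- sample(seq_len(gene_len - len + 1), 1)
            ev$start_nt <- st
            ev$end_nt <- st + len - 1
          }
          ev_list[[length(ev_list) + 1]] <- ev
        }
        if (sequences) {
          cfg <- quartetSimConfig(n_codons, k_par, k_orth, ka_ks_ratio,
                                  if (length(ev_list)) ev_list else
                                    list(type = "none"))
          sim <- simulateQuartet(cfg, id = sprintf("pair%05d", pid))
          sq <- as.character(sim$seqs)
          seqs[c(ids["A1"], ids["A2"], ids["B1"], ids["B2"])] <-
            list(sq[["P1"]], sq[["P2"]], sq[["S1"]], sq[["S2"]])
        } else {
          seqs[c(ids["A1"], ids["A2"], ids["B1"], ids["B2"])] <-
            list(.placeholderCds(n_codons), .placeholderCds(n_codons),
                 .placeholderCds(n_codons), .placeholderCds(n_codons))
        }
        gene_of <- c(P1 = ids[["A1"]], P2 = ids[["A2"]],
                     S1 = ids[["B1"]], S2 = ids[["B2"]])
        typ <- setNames(rep("none", 2), c("A", "B"))
        acc_gene <- don_gene <- setNames(rep(NA_character_, 2), c("A", "B"))
        trs <- tre <- setNames(rep(NA_integer_, 2), c("A", "B"))
        for (ev in ev_list) {
          g <- if (startsWith(ev$acceptor, "P")) "A" else "B"
          typ[g] <- if (ev$type == "whole") "WCV" else "PCV"
          acc_gene[g] <- gene_of[[ev$acceptor]]
          don_gene[g] <- gene_of[[ev$donor]]
          trs[g] <- if (ev$type == "whole") 1L else ev$start_nt
          tre[g] <- if (ev$type == "whole") gene_len else ev$end_nt
        }
        truth[[pid]] <- data.frame(
          pair_id = sprintf("pair%05d", pid),
          p1 = ids[["A1"]], p2 = ids[["A2"]],
          s1 = ids[["B1"]], s2 = ids[["B2"]],
          chrom_a = c1, chrom_b = c2, index = j,
          genome = c("A", "B"),
          converted = unname(typ != "none"),
          type = unname(typ),
          acceptor = unname(acc_gene), donor = unname(don_gene),
          tract_start = unname(trs), tract_end = unname(tre),
          stringsAsFactors = FALSE)
        # paralog pair within each genome plus the two ortholog pairs
        pair_rows[[length(pair_rows) + 1]] <- data.frame(
          gene_a = c(ids[["A1"]], ids[["B1"]], ids[["A1"]], ids[["A2"]]),
          gene_b = c(ids[["A2"]], ids[["B2"]], ids[["B1"]], ids[["B2"]]),
          stringsAsFactors = FALSE)
        dup_flag <- c(TRUE, TRUE, TRUE, TRUE)
        conv_flag <- c(ids[["A1"]], ids[["A2"]], ids[["B1"]],
                       ids[["B2"]]) %in% stats::na.omit(acc_gene)
      } else {
        # singleton genes: background gene density only; their B-side
        # orthologs exist but enter no homolog pair row, mirroring a
        # pair table restricted to duplicate-derived homology
        for (w in 1:2) {
          if (sequences) {
            anc <- .randomCodingSeq(n_codons)
            seqs[[ids[[paste0("A", w)]]]] <-
              .codonsToString(.evolve(anc, k_orth / 2, ka_ks_ratio))
            seqs[[ids[[paste0("B", w)]]]] <-
              .codonsToString(.evolve(anc, k_orth / 2, ka_ks_ratio))
          } else {
            seqs[[ids[[paste0("A", w)]]]] <- .placeholderCds(n_codons)
            seqs[[ids[[paste0("B", w)]]]] <- .placeholderCds(n_codons)
          }
        }
        dup_flag <- c(FALSE, FALSE, FALSE, FALSE)
        conv_flag <- c(FALSE, FALSE, FALSE, FALSE)
      }
      gtruth[[length(gtruth) + 1]] <- data.frame(
        gene_id = c(ids[["A1"]], ids[["A2"]], ids[["B1"]], ids[["B2"]]),
        genome = c("A", "A", "B", "B"),
        chromosome = c(c1, c2, c1, c2),
        midpoint = start + gene_len / 2,
        is_duplicate = dup_flag, converted = conv_flag,
        stringsAsFactors = FALSE)
      for (g in c("A", "B")) for (w in 1:2) {
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = ids[[paste0(g, w)]], genome = g,
          chromosome = if (w == 1) c1 else c2,
          start = start, end = start + gene_len - 1, strand = "+",
          stringsAsFactors = FALSE)
      }
    }
  }
  coords <- do.call(rbind, rows)
  seqv <- unlist(seqs)
  mk <- function(g) {
    cc <- coords[coords$genome == g, ]
    GeneCatalog(cc[, c("gene_id", "chromosome", "start", "end", "strand")],
                seqv[cc$gene_id], genome = g)
  }
  empty_pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                            stringsAsFactors = FALSE)
  list(catalogA = mk("A"), catalogB = mk("B"),
       pairs = if (length(pair_rows)) do.call(rbind, pair_rows) else
         empty_pairs,
       truth = if (pid > 0) do.call(rbind, truth) else
         data.frame(pair_id = character(0)),
       gene_truth = do.call(rbind, gtruth))
}

#' Simulate a paired expression (TPM) table
#'
#' Each gene pair receives a shared log-normal base abundance and a
#' log2 fold change drawn from a centered normal whose spread depends on
#' conversion status; converted pairs are drawn with the smaller spread,
#' emulating their more similar expression. A configurable fraction of
#' genes is silenced to zero TPM to exercise the non-expressed filter.
#'
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param converted Logical vector, one flag per pair.
#' @param effect_cfg List: `mean_tpm_converted`, `mean_tpm_nonconverted`
#'   (marginal per-gene mean TPM), `sdlog` (log-normal shape),
#'   `spread_converted`, `spread_nonconverted` (sd of the log2 fold
#'   change), `zero_rate` (probability a gene is silenced).
#' @param seed Optional integer seed.
#' @return data.frame `gene_id`, `tpm`.
#' @export
simulateExpression <- function(pairs, converted,
                               effect_cfg = list(
                                 mean_tpm_converted = 35.69,
                                 mean_tpm_nonconverted = 47.04,
                                 sdlog = 1.0,
                                 spread_converted = 1.56,
                                 spread_nonconverted = 1.76,
                                 zero_rate = 0.02),
                               seed = NULL) {
  stopifnot(nrow(pairs) == length(converted))
  if (effect_cfg$spread_converted < 0 || effect_cfg$spread_nonconverted < 0)
    stop("fold-change spreads must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(pairs)
  m <- ifelse(converted, effect_cfg$mean_tpm_converted,
              effect_cfg$mean_tpm_nonconverted)
  spread <- ifelse(converted, effect_cfg$spread_converted,
                   effect_cfg$spread_nonconverted)
  # de-bias the base abundance so the marginal per-gene mean TPM equals
  # the configured group mean despite the log-fold-change factor
  fc_bias <- (log(2) / 2)^2 * spread^2 / 2
  base <- rlnorm(n, meanlog = log(m) - effect_cfg$sdlog^2 / 2 - fc_bias,
                 sdlog = effect_cfg$sdlog)
  fc <- rnorm(n, 0, spread)
  tpm_a <- base * 2^(fc / 2)
  tpm_b <- base * 2^(-fc / 2)
  tpm <- c(tpm_a, tpm_b)
  zero <- runif(2 * n) < effect_cfg$zero_rate
  tpm[zero] <- 0
  data.frame(gene_id = c(pairs$gene_a, pairs$gene_b), tpm = tpm,
             stringsAsFactors = FALSE)
}
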