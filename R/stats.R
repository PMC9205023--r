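# Genome-scale summaries of conversion calls: rates, positional
# analyses, duplicate-density correlation, group comparisons,
# expression divergence and GO enrichment.

#' A labeled rate record
#'
#' @param numerator,denominator Non-negative integer counts,
#'   `numerator <= denominator`, `denominator > 0`.
#' @param label Description of the rate.
#' @return data.frame `label`, `numerator`, `denominator`, `percent`
#'   (`round(100 * n / d, 2)`).
#' @examples
#' rate(304, 4813, "converted paralogs")  # 6.32
#' @export
rate <- function(numerator, denominator, label = "") {
  if (denominator <= 0) stop("denominator must be positive")
  if (numerator < 0 || numerator > denominator)
    stop("need 0 <= numerator <= denominator")
  data.frame(label = label, numerator = as.integer(numerator),
             denominator = as.integer(denominator),
             percent = round(100 * numerator / denominator, 2),
             stringsAsFactors = FALSE)
}

#' Conversion rates by chromosome-length decile
#'
#' Each duplicate is assigned by its midpoint to a decile of its
#' chromosome's length; rates are reported for the first decile, the
#' last decile, and the pooled middle, with a one-way ANOVA across the
#' three positional groups using per-chromosome group rates as
#' observations. Chromosomes without duplicates are kept in the totals
#' but excluded from the ANOVA.
#'
#' @param gene_tab data.frame with `gene_id`, `chromosome`, `midpoint`,
#'   `is_duplicate`, `converted` (one genome's genes).
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp);
#'   defaults to the maximum gene midpoint per chromosome.
#' @return List: `rates` (RateRecords for first/middle/last), `by_decile`
#'   (10-row count table), `anova_p`.
#' @export
decileConversionRates <- function(gene_tab, chrom_lengths = NULL) {
  dup <- gene_tab[gene_tab$is_duplicate, , drop = FALSE]
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(gene_tab$midpoint, gene_tab$chromosome, max)
  dec <- pmin(pmax(ceiling(10 * dup$midpoint /
                             chrom_lengths[dup$chromosome]), 1), 10)
  grp <- ifelse(dec == 1, "first", ifelse(dec == 10, "last", "middle"))
  by_dec <- data.frame(decile = 1:10,
                       duplicates = as.integer(table(factor(dec, 1:10))),
                       converted = as.integer(tapply(dup$converted,
                                                     factor(dec, 1:10), sum,
                                                     default = 0)))
  by_dec$converted[is.na(by_dec$converted)] <- 0L
  rates <- do.call(rbind, lapply(c("first", "middle", "last"), function(g) {
    n <- sum(dup$converted[grp == g])
    d <- sum(grp == g)
    if (d == 0) return(NULL)
    rate(n, d, paste0(g, "_decile"))
  }))
  per_chrom <- aggregate(list(conv = dup$converted),
                         by = list(chromosome = dup$chromosome, group = grp),
                         FUN = mean)
  keep <- names(which(table(per_chrom$chromosome) == 3))
  per_chrom <- per_chrom[per_chrom$chromosome %in% keep, ]
  anova_p <- if (length(unique(per_chrom$group)) >= 2 &&
                 nrow(per_chrom) >= 4) {
    oneway.test(conv ~ group, data = per_chrom, var.equal = TRUE)$p.value
  } else NA_real_
  list(rates = rates, by_decile = by_dec, anova_p = anova_p)
}

#' Windowed duplicate density vs conversion rate, per chromosome
#'
#' Chromosomes are tiled with windows of `window_bp` laid from both
#' termini toward the center (the center window may be short). Per
#' window: duplicate density = duplicates / all genes; conversion rate
#' = converted / duplicates (undefined without duplicates). Per
#' chromosome, the Pearson correlation between density and rate over
#' windows with a defined rate; chromosomes with fewer than 3 such
#' windows are flagged undefined.
#'
#' @param gene_tab As in [decileConversionRates()].
#' @param window_bp Window size (default 1e6).
#' @param chrom_lengths Optional named lengths.
#' @return List: `windows` (per-window table), `correlations`
#'   (`chromosome`, `r`, `p`, `n_windows`, `defined`).
#' @export
windowDensityCorrelation <- function(gene_tab, window_bp = 1e6,
                                     chrom_lengths = NULL) {
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(gene_tab$midpoint, gene_tab$chromosome, max)
  win_rows <- list(); cor_rows <- list()
  for (ch in names(chrom_lengths)) {
    gt <- gene_tab[gene_tab$chromosome == ch, , drop = FALSE]
    len <- chrom_lengths[[ch]]
    # windows from each terminus toward the center
    n_half <- floor(len / (2 * window_bp))
    starts <- c(seq_len(n_half) - 1, 0) * window_bp
    bounds_lo <- c((seq_len(n_half) - 1) * window_bp,
                   if (len - 2 * n_half * window_bp > 0)
                     n_half * window_bp else NULL,
                   len - (seq_len(n_half)) * window_bp)
    bounds_hi <- c((seq_len(n_half)) * window_bp,
                   if (len - 2 * n_half * window_bp > 0)
                     len - n_half * window_bp else NULL,
                   len - (seq_len(n_half) - 1) * window_bp)
    ord <- order(bounds_lo)
    bounds_lo <- bounds_lo[ord]; bounds_hi <- bounds_hi[ord]
    wi <- findInterval(gt$midpoint, c(bounds_lo, Inf),
                       rightmost.closed = FALSE)
    wi[wi < 1] <- 1; wi[wi > length(bounds_lo)] <- length(bounds_lo)
    wtab <- data.frame(chromosome = ch,
                       window = seq_along(bounds_lo),
                       start = bounds_lo + 1, end = bounds_hi,
                       n_genes = as.integer(table(factor(wi,
                         seq_along(bounds_lo)))),
                       stringsAsFactors = FALSE)
    wtab$n_dup <- as.integer(tapply(gt$is_duplicate,
                                    factor(wi, seq_along(bounds_lo)),
                                    sum, default = 0))
    wtab$n_conv <- as.integer(tapply(gt$converted & gt$is_duplicate,
                                     factor(wi, seq_along(bounds_lo)),
                                     sum, default = 0))
    wtab$n_dup[is.na(wtab$n_dup)] <- 0L
    wtab$n_conv[is.na(wtab$n_conv)] <- 0L
    wtab$density <- ifelse(wtab$n_genes > 0, wtab$n_dup / wtab$n_genes, NA)
    wtab$conv_rate <- ifelse(wtab$n_dup > 0, wtab$n_conv / wtab$n_dup, NA)
    win_rows[[ch]] <- wtab
    ok <- complete.cases(wtab[, c("density", "conv_rate")])
    if (sum(ok) >= 3 && sd(wtab$density[ok]) > 0 &&
        sd(wtab$conv_rate[ok]) > 0) {
      ct <- cor.test(wtab$density[ok], wtab$conv_rate[ok])
      cor_rows[[ch]] <- data.frame(chromosome = ch, r = unname(ct$estimate),
                                   p = ct$p.value, n_windows = sum(ok),
                                   defined = TRUE, stringsAsFactors = FALSE)
    } else {
      cor_rows[[ch]] <- data.frame(chromosome = ch, r = NA_real_,
                                   p = NA_real_, n_windows = sum(ok),
                                   defined = FALSE, stringsAsFactors = FALSE)
    }
  }
  list(windows = do.call(rbind, win_rows),
       correlations = do.call(rbind, cor_rows))
}

#' Two-group or multi-group comparison
#'
#' Two-sided two-sample Student t-test (pooled variance) or one-way
#' ANOVA.
#'
#' @param values_a,values_b Numeric vectors (t-test), or pass a list of
#'   groups as `values_a` with `test = "anova"`.
#' @param test `"t"` or `"anova"`.
#' @return List `statistic`, `p`, `degenerate` (TRUE when the pooled
#'   variance is zero and identical groups force p = 1).
#' @export
compareGroups <- function(values_a, values_b = NULL, test = c("t", "anova")) {
  test <- match.arg(test)
  if (test == "t") {
    a <- values_a[is.finite(values_a)]; b <- values_b[is.finite(values_b)]
    if (length(a) < 2 || length(b) < 2)
      stop("each group needs at least two finite values")
    if (sd(c(a - mean(a), b - mean(b))) == 0) {
      return(list(statistic = 0,
                  p = if (mean(a) == mean(b)) 1 else NA_real_,
                  degenerate = TRUE))
    }
    ht <- t.test(a, b, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p = ht$p.value,
         degenerate = FALSE)
  } else {
    groups <- if (is.list(values_a)) values_a else list(values_a, values_b)
    if (length(groups) < 2) stop("ANOVA needs at least two groups")
    v <- unlist(groups)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    if (sd(v - ave(v, g)) == 0)
      return(list(statistic = 0, p = 1, degenerate = TRUE))
    ht <- oneway.test(v ~ g, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p = ht$p.value,
         degenerate = FALSE)
  }
}

#' Substitution-rate comparison of converted vs nonconverted pairs
#'
#' Group means of the JC-corrected nonsynonymous (`pn`) and synonymous
#' (`ps`) distances and their ratio, compared between converted and
#' nonconverted gene pairs by the pooled-variance Student t-test — the
#' per-genome paralog table and the ortholog table of the headline
#' comparisons.
#'
#' @param pairstats data.frame with `pn`, `ps` columns (one row per
#'   gene pair, e.g. row-bound [ng86()] output).
#' @param converted Logical per pair.
#' @return data.frame: `measure` (`pn`, `ps`, `pn_ps`),
#'   `mean_converted`, `mean_nonconverted`, `p_value`.
#' @export
substitutionRateComparison <- function(pairstats, converted) {
  stopifnot(nrow(pairstats) == length(converted))
  ratio <- ifelse(pairstats$ps > 0, pairstats$pn / pairstats$ps, NA_real_)
  vals <- list(pn = pairstats$pn, ps = pairstats$ps, pn_ps = ratio)
  out <- lapply(names(vals), function(nm) {
    v <- vals[[nm]]
    a <- v[converted & is.finite(v)]
    b <- v[!converted & is.finite(v)]
    p <- if (length(a) >= 2 && length(b) >= 2)
      compareGroups(a, b, "t")$p else NA_real_
    data.frame(measure = nm, mean_converted = mean(a),
               mean_nonconverted = mean(b), p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Expression divergence of converted vs nonconverted duplicate pairs
#'
#' Genes with zero TPM are removed first (non-expressed filter); a pair
#' is evaluated only when both members remain. A pair is divergent when
#' `(max(tpm) + c) / (min(tpm) + c) >= fold_cutoff` with pseudocount
#' `c`. Reports the divergent proportion per group as RateRecords, the
#' mean TPM per group (over member genes) and the Student t-test
#' p-value of the mean comparison.
#'
#' @param tpm data.frame `gene_id`, `tpm`.
#' @param pairs data.frame `gene_a`, `gene_b`.
#' @param converted Logical per pair.
#' @param fold_cutoff Fold-change threshold (default 2).
#' @param pseudocount Added to both TPM values (default 0.1).
#' @return List: `proportions` (RateRecords), `mean_tpm` (per group),
#'   `t_p` (mean-TPM comparison), `pair_table`.
#' @export
expressionDivergence <- function(tpm, pairs, converted, fold_cutoff = 2,
                                 pseudocount = 0.1) {
  stopifnot(nrow(pairs) == length(converted))
  expr <- setNames(tpm$tpm, tpm$gene_id)
  expr <- expr[expr > 0]
  ok <- pairs$gene_a %in% names(expr) & pairs$gene_b %in% names(expr)
  pt <- data.frame(gene_a = pairs$gene_a[ok], gene_b = pairs$gene_b[ok],
                   converted = converted[ok], stringsAsFactors = FALSE)
  if (nrow(pt) == 0) stop("no pair with both members expressed")
  ta <- expr[pt$gene_a]; tb <- expr[pt$gene_b]
  pt$fold <- (pmax(ta, tb) + pseudocount) / (pmin(ta, tb) + pseudocount)
  pt$divergent <- pt$fold >= fold_cutoff
  props <- list(); means <- list(); gv <- list()
  for (g in c("converted", "nonconverted")) {
    sel <- if (g == "converted") pt$converted else !pt$converted
    if (!any(sel)) next
    props[[g]] <- rate(sum(pt$divergent[sel]), sum(sel),
                       paste0(g, "_divergent"))
    gv[[g]] <- c(ta[sel], tb[sel])
    means[[g]] <- mean(gv[[g]])
  }
  t_p <- if (length(gv) == 2 && min(lengths(gv)) >= 2)
    compareGroups(gv$converted, gv$nonconverted, "t")$p else NA_real_
  list(proportions = do.call(rbind, props),
       mean_tpm = unlist(means), t_p = t_p, pair_table = pt)
}

#' GO term enrichment of converted genes by Pearson chi-square
#'
#' Per GO term, the 2x2 table (converted vs not) x (in term vs not)
#' over the duplicate universe, tested by Pearson's chi-square without
#' continuity correction. Reports the proportion of converted genes and
#' of all duplicates carrying each term, the raw p-value (flagged when
#' any expected cell is below 1) and a Benjamini-Hochberg q-value.
#'
#' @param go_map data.frame `gene_id`, `term`.
#' @param converted_set Character vector of converted gene ids (must be
#'   a subset of the universe).
#' @param universe Character vector of all duplicate gene ids.
#' @return data.frame per term: `term`, `n_converted`, `n_universe`,
#'   `prop_converted`, `prop_universe`, `chisq`, `p`, `low_count`, `q`.
#' @export
goEnrichment <- function(go_map, converted_set, universe) {
  if (!all(converted_set %in% universe))
    stop("converted genes must all be in the universe")
  go_map <- go_map[go_map$gene_id %in% universe, , drop = FALSE]
  n_conv <- length(converted_set)
  n_all <- length(universe)
  rows <- lapply(split(go_map$gene_id, go_map$term), function(members) {
    members <- unique(members)
    a <- sum(converted_set %in% members)        # converted, in term
    b <- n_conv - a                              # converted, not in term
    c_ <- length(members) - a                    # nonconverted, in term
    d <- (n_all - n_conv) - c_
    tab <- matrix(c(a, b, c_, d), 2, 2)
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (sd(c(a / max(n_conv, 1), c_ / max(n_all - n_conv, 1))) == 0 ||
        all(tab[1, ] == 0) || all(tab[2, ] == 0)) {
      chisq <- 0; p <- 1
    } else {
      ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
      chisq <- unname(ht$statistic); p <- ht$p.value
    }
    data.frame(n_converted = a, n_universe = length(members),
               prop_converted = if (n_conv) a / n_conv else NA_real_,
               prop_universe = length(members) / n_all,
               chisq = chisq, p = p, low_count = any(expd < 1))
  })
  out <- do.call(rbind, rows)
  out <- cbind(term = names(rows), out)
  rownames(out) <- NULL
  out$q <- p.adjust(out$p, method = "BH")
  out
}
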