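test_that("rate records reproduce printed-count arithmetic", {
  expect_equal(rate(304, 4813)$percent, 6.32)
  expect_equal(rate(0, 100)$percent, 0)
  expect_equal(rate(28, 4813)$percent, 0.58)
  r <- rate(53, 1231, "first decile")
  expect_equal(r$percent, round(100 * r$numerator / r$denominator, 2))
  expect_error(rate(1, 0))
  expect_error(rate(5, 3))
})

test_that("decile partition conserves counts and is calibrated on nulls", {
  set.seed(81)
  sim <- simulateGenomePair(4, 500, duplicate_density = 0.5,
                            converted_rate = 0.1, sequences = FALSE,
                            seed = 82)
  gt <- sim$gene_truth[sim$gene_truth$genome == "A", ]
  res <- decileConversionRates(gt)
  expect_equal(sum(res$by_decile$converted),
               sum(gt$converted[gt$is_duplicate]))
  expect_equal(sum(res$by_decile$duplicates), sum(gt$is_duplicate))
  expect_equal(sum(res$rates$numerator),
               sum(gt$converted[gt$is_duplicate]))
  # uniform placement: the three positional groups differ only by noise
  ps <- replicate(12, {
    s <- simulateGenomePair(4, 400, duplicate_density = 0.5,
                            converted_rate = 0.1, sequences = FALSE)
    g <- s$gene_truth[s$gene_truth$genome == "A", ]
    decileConversionRates(g)$anova_p
  })
  expect_gte(mean(ps > 0.05, na.rm = TRUE), 0.75)
})

test_that("window correlation handles constructed and degenerate cases", {
  # conversion rate equal to density by construction: r = 1
  gt <- data.frame(
    gene_id = sprintf("g%04d", 1:4000), genome = "A", chromosome = "chr1",
    midpoint = seq(500, by = 2500, length.out = 4000))
  u <- gt$midpoint / max(gt$midpoint)
  dens <- 0.2 + 0.6 * u
  set.seed(83)
  gt$is_duplicate <- TRUE
  gt$converted <- runif(4000) < dens
  wc <- windowDensityCorrelation(gt, window_bp = 1e6)
  w <- wc$windows
  # density is 1 everywhere here, so make a direct construction instead:
  gt2 <- gt
  gt2$is_duplicate <- runif(4000) < dens
  gt2$converted <- gt2$is_duplicate & (runif(4000) < dens)
  wc2 <- windowDensityCorrelation(gt2, window_bp = 1e6)
  expect_true(wc2$correlations$defined)
  expect_gt(wc2$correlations$r, 0.5)
  # windows tile the chromosome without overlap
  w2 <- wc2$windows
  expect_true(all(w2$start[-1] == w2$end[-nrow(w2)] + 1))
  expect_equal(sum(w2$n_genes), 4000)
  # constant density: zero variance, undefined correlation
  expect_false(wc$correlations$defined[1])
  # random windows: r equals the textbook formula (checked in the
  # simulator test as well)
  ok <- complete.cases(w2[, c("density", "conv_rate")])
  expect_equal(wc2$correlations$r,
               oracle_pearson_r(w2$density[ok], w2$conv_rate[ok]))
})

test_that("group comparisons match closed forms", {
  # identical groups: t = 0, p = 1
  res <- compareGroups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # hand-computable case
  res2 <- compareGroups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res2$statistic, oracle_pooled_t(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res2$statistic, -3 / sqrt(2 / 3))
  # power check
  set.seed(84)
  res3 <- compareGroups(rnorm(200), rnorm(200, 2))
  expect_lt(res3$p, 1e-10)
  # anova degenerate and regular paths
  expect_equal(compareGroups(list(c(1, 1), c(1, 1), c(1, 1)),
                             test = "anova")$p, 1)
  a4 <- compareGroups(list(rnorm(50), rnorm(50, 3)), test = "anova")
  expect_lt(a4$p, 1e-6)
  expect_error(compareGroups(1, c(1, 2)))
})

test_that("expression divergence applies the filter, cutoff and t-test", {
  tpm <- data.frame(gene_id = c("a1", "b1", "a2", "b2", "a3", "b3"),
                    tpm = c(10, 30, 10, 10, 0, 5))
  pairs <- data.frame(gene_a = c("a1", "a2", "a3"),
                      gene_b = c("b1", "b2", "b3"))
  res <- expressionDivergence(tpm, pairs, c(FALSE, FALSE, FALSE),
                              pseudocount = 0)
  # the zero-TPM pair is removed, (10,30) is divergent, (10,10) is not
  expect_equal(nrow(res$pair_table), 2)
  expect_equal(res$pair_table$divergent, c(TRUE, FALSE))
  expect_equal(res$proportions$numerator, 1)
  expect_equal(res$proportions$denominator, 2)
  expect_equal(res$proportions$percent, 50)
  # published proportion arithmetic
  expect_equal(rate(133, 255)$percent, 52.16)
  # group means and t-test appear once both groups exist
  set.seed(85)
  n <- 300
  pr <- data.frame(gene_a = sprintf("x%03d", 1:n),
                   gene_b = sprintf("y%03d", 1:n))
  conv <- rep(c(TRUE, FALSE), n / 2)
  tp <- simulateExpression(pr, conv, seed = 86)
  r2 <- expressionDivergence(tp, pr, conv)
  expect_equal(sort(names(r2$mean_tpm)),
               c("converted", "nonconverted"))
  expect_true(is.finite(r2$t_p))
})

test_that("substitution-rate group comparison mirrors the t-test", {
  set.seed(88)
  ps <- data.frame(pn = c(rnorm(40, 0.08, 0.02), rnorm(40, 0.09, 0.02)),
                   ps = c(rnorm(40, 0.22, 0.05), rnorm(40, 0.26, 0.05)))
  conv <- rep(c(TRUE, FALSE), each = 40)
  tab <- substitutionRateComparison(ps, conv)
  expect_equal(tab$measure, c("pn", "ps", "pn_ps"))
  expect_equal(tab$mean_converted[2], mean(ps$ps[conv]))
  expect_equal(tab$mean_nonconverted[2], mean(ps$ps[!conv]))
  expect_equal(tab$p_value[1],
               compareGroups(ps$pn[conv], ps$pn[!conv])$p)
  expect_true(all(is.finite(tab$p_value)))
})

test_that("GO enrichment is a plain Pearson chi-square per term", {
  universe <- sprintf("g%03d", 1:300)
  conv <- universe[1:100]
  # identical proportions: statistic 0, p 1
  go_eq <- data.frame(gene_id = c(conv[1:10], universe[101:120]),
                      term = "T1")
  res <- goEnrichment(go_eq, conv, universe)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  # formula oracle on random tables
  set.seed(87)
  for (i in 1:50) {
    members <- sample(universe, sample(20:80, 1))
    gm <- data.frame(gene_id = members, term = "T")
    r <- goEnrichment(gm, conv, universe)
    a <- sum(conv %in% members)
    tab <- matrix(c(a, 100 - a, length(members) - a,
                    200 - (length(members) - a)), 2, 2)
    expect_equal(r$chisq, oracle_chisq(tab), tolerance = 1e-9)
  }
  # converted genes outside the universe are an error
  expect_error(goEnrichment(go_eq, c(conv, "zzz"), universe))
  # q-values present and within [0, 1]
  gm2 <- rbind(data.frame(gene_id = sample(universe, 40), term = "A"),
               data.frame(gene_id = sample(universe, 40), term = "B"))
  r2 <- goEnrichment(gm2, conv, universe)
  expect_true(all(r2$q >= 0 & r2$q <= 1))
})
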