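test_that("degenerate configurations behave exactly", {
  # no divergence, no conversion: four identical sequences, empty truth
  s <- simulateQuartet(quartetSimConfig(n_codons = 50, k_par = 0,
                                        k_orth = 0), seed = 1)
  expect_equal(length(unique(as.character(s$seqs))), 1)
  expect_equal(nrow(s$truth), 0)
  # whole conversion at the present: acceptor identical to donor
  s <- simulateQuartet(quartetSimConfig(
    conversion = list(type = "whole", acceptor = "P2", donor = "P1",
                      time_fraction = 1)), seed = 2)
  expect_identical(as.character(s$seqs[["P1"]]),
                   as.character(s$seqs[["P2"]]))
  expect_equal(s$truth$type, "WCV")
  expect_equal(s$truth$tract_start, 1)
  expect_equal(s$truth$tract_end, 1500)
})

test_that("invalid configurations are rejected", {
  expect_error(quartetSimConfig(k_par = 0.1, k_orth = 0.2))
  expect_error(quartetSimConfig(k_par = 5))  # JC saturation
  expect_error(quartetSimConfig(conversion = list(
    type = "tract", start_nt = 0, end_nt = 50, acceptor = "P1",
    donor = "P2", time_fraction = 1)))
  expect_error(quartetSimConfig(conversion = list(
    type = "whole", acceptor = "P1", donor = "S1", time_fraction = 1)))
})

test_that("NG86 Ks of simulated pairs recovers the configured targets", {
  set.seed(31)
  cfg <- quartetSimConfig(n_codons = 500, k_par = 0.25, k_orth = 0.12)
  ks_par <- ks_orth <- numeric(100)
  for (i in 1:100) {
    s <- simulateQuartet(cfg)
    aln <- codonAlignment(as.character(s$seqs))
    ks_par[i] <- ng86(aln, c("P1", "P2"))$ks
    ks_orth[i] <- ng86(aln, c("P1", "S1"))$ks
  }
  expect_lt(abs(mean(ks_par) - 0.25), 0.02)
  expect_lt(abs(mean(ks_orth) - 0.12), 0.02)
})

test_that("whole conversion at the present zeroes the paralog Ks exactly", {
  s <- simulateQuartet(quartetSimConfig(
    conversion = list(type = "whole", acceptor = "P1", donor = "P2",
                      time_fraction = 1)), seed = 33)
  aln <- codonAlignment(as.character(s$seqs))
  expect_equal(ng86(aln, c("P1", "P2"))$ks, 0)
})

test_that("quartet sets honor event fractions and seeded determinism", {
  r0 <- simulateQuartetSet(40, 0, 0, quartetSimConfig(n_codons = 30),
                           seed = 5)
  expect_equal(nrow(r0$truth), 0)
  r1 <- simulateQuartetSet(40, 0, 1, quartetSimConfig(n_codons = 30),
                           seed = 5)
  expect_equal(sum(r1$truth$type == "WCV"), 40)
  r2a <- simulateQuartetSet(10, 0.5, 0.2, quartetSimConfig(n_codons = 30),
                            seed = 6)
  r2b <- simulateQuartetSet(10, 0.5, 0.2, quartetSimConfig(n_codons = 30),
                            seed = 6)
  expect_identical(
    lapply(r2a$quartets, function(q) as.character(q$seqs)),
    lapply(r2b$quartets, function(q) as.character(q$seqs)))
  expect_identical(r2a$truth, r2b$truth)
  expect_equal(sum(r2a$truth$type == "PCV"), 5)
  expect_equal(sum(r2a$truth$type == "WCV"), 2)
  tl <- r2a$truth$tract_end - r2a$truth$tract_start + 1
  expect_true(all(tl[r2a$truth$type == "PCV"] >= 30 &
                    tl[r2a$truth$type == "PCV"] <= 120))
  expect_error(simulateQuartetSet(10, 0.7, 0.7))
})

test_that("genome-pair layout respects density profiles and coordinates", {
  sim <- simulateGenomePair(2, 400, duplicate_density = 0.5,
                            converted_rate = 0.3, sequences = FALSE,
                            seed = 7)
  gt <- sim$gene_truth
  gr <- geneRanges(sim$catalogA)
  expect_true(all(GenomicRanges::start(gr) <= GenomicRanges::end(gr)))
  oi <- orderIndex(sim$catalogA)
  per_chrom <- split(oi, as.character(GenomicRanges::seqnames(gr)))
  for (v in per_chrom) expect_equal(sort(unname(v)), seq_along(v) - 1L)
  # constant profiles: duplicate rate near 0.5, conversion near 0.3
  expect_lt(abs(mean(gt$is_duplicate[gt$genome == "A"]) - 0.5), 0.07)
  tr <- sim$truth
  expect_lt(abs(mean(tr$converted) - 0.3), 0.08)
  # zero duplicate density: empty pair table
  s0 <- simulateGenomePair(2, 50, duplicate_density = 0,
                           sequences = FALSE, seed = 8)
  expect_equal(nrow(s0$pairs), 0)
  expect_error(simulateGenomePair(2, 10, duplicate_density = 1.5,
                                  sequences = FALSE))
})

test_that("conversion rate tracks duplicate density along chromosomes", {
  # a strongly contrasted density profile, with the conversion rate
  # proportional to it
  prof <- function(u) 0.05 + 0.9 * u
  sim <- simulateGenomePair(2, 2000, duplicate_density = prof,
                            converted_rate = prof,
                            sequences = FALSE, seed = 9)
  gtA <- sim$gene_truth[sim$gene_truth$genome == "A", ]
  wc <- windowDensityCorrelation(gtA)
  ok <- wc$correlations$defined
  expect_true(all(wc$correlations$r[ok] > 0.8))
  # and the windows table matches the direct Pearson formula
  w1 <- wc$windows[wc$windows$chromosome == "chr01", ]
  use <- complete.cases(w1[, c("density", "conv_rate")])
  expect_equal(wc$correlations$r[wc$correlations$chromosome == "chr01"],
               oracle_pearson_r(w1$density[use], w1$conv_rate[use]),
               tolerance = 1e-12)
})

test_that("expression tables reflect conversion-dependent divergence", {
  pairs <- data.frame(gene_a = sprintf("a%04d", 1:5000),
                      gene_b = sprintf("b%04d", 1:5000))
  converted <- rep(FALSE, 5000)
  # spread chosen so the analytic divergent fraction is 55%:
  # P(|fc| >= 1) = 2 * pnorm(-1 / sigma) = 0.55 => sigma = 1.6723
  cfg <- list(mean_tpm_converted = 35.69, mean_tpm_nonconverted = 47.04,
              sdlog = 1.0, spread_converted = 0,
              spread_nonconverted = 1.6723, zero_rate = 0)
  tpm <- simulateExpression(pairs, converted, cfg, seed = 10)
  res <- expressionDivergence(tpm, pairs, converted, fold_cutoff = 2,
                              pseudocount = 0)
  expect_lt(abs(res$proportions$percent[1] - 55), 3)
  # zero spread: converted pairs have fold change exactly 1
  conv2 <- rep(TRUE, 100)
  tpm2 <- simulateExpression(pairs[1:100, ], conv2, cfg, seed = 11)
  res2 <- expressionDivergence(tpm2, pairs[1:100, ], conv2,
                               pseudocount = 0)
  expect_true(all(res2$pair_table$fold == 1))
  # determinism
  t1 <- simulateExpression(pairs[1:50, ], converted[1:50], cfg, seed = 12)
  t2 <- simulateExpression(pairs[1:50, ], converted[1:50], cfg, seed = 12)
  expect_identical(t1, t2)
  cfg_bad <- cfg; cfg_bad$spread_converted <- -1
  expect_error(simulateExpression(pairs[1:10, ], converted[1:10], cfg_bad))
})
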