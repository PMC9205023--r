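mk_catalog <- function(n, chrom = "chr1", genome = "G", prefix = "g") {
  coords <- data.frame(gene_id = sprintf("%s%03d", prefix, seq_len(n)),
                       chromosome = chrom,
                       start = seq_len(n) * 1000,
                       end = seq_len(n) * 1000 + 500,
                       strand = "+")
  cds <- setNames(rep("ATGGCTGCA", n), coords$gene_id)
  GeneCatalog(coords, cds, genome = genome)
}

test_that("large gene families are removed by connected components", {
  # one hub gene matched by 60 partners: the whole family goes
  hub <- data.frame(gene_a = "hub", gene_b = sprintf("m%02d", 1:60))
  small <- data.frame(gene_a = c("x1", "y1"), gene_b = c("x2", "y2"))
  out <- filterLargeFamilies(rbind(hub, small), 50)
  expect_equal(sort(out$gene_a), c("x1", "y1"))
  # all families of size 2: unchanged
  expect_equal(nrow(filterLargeFamilies(small, 50)), 2)
  # random graph vs explicit union-find-style recomputation via igraph
  set.seed(41)
  genes <- sprintf("r%03d", 1:60)
  rnd <- data.frame(gene_a = sample(genes, 120, TRUE),
                    gene_b = sample(genes, 120, TRUE))
  rnd <- rnd[rnd$gene_a != rnd$gene_b, ]
  out <- filterLargeFamilies(rnd, 10)
  # oracle: recompute membership sizes independently
  uf <- setNames(seq_along(genes), genes)
  find <- function(i) { while (uf[i] != i) i <- uf[i]; i }
  for (k in seq_len(nrow(rnd))) {
    ra <- find(match(rnd$gene_a[k], genes))
    rb <- find(match(rnd$gene_b[k], genes))
    if (ra != rb) uf[ra] <- rb
  }
  roots <- vapply(seq_along(genes), find, numeric(1))
  fam_size <- table(roots)
  sz <- function(g) fam_size[[as.character(roots[match(g, genes)])]]
  keep <- vapply(seq_len(nrow(rnd)),
                 function(k) sz(rnd$gene_a[k]) < 10 &&
                   sz(rnd$gene_b[k]) < 10, logical(1))
  expect_equal(nrow(out), sum(keep))
})

test_that("diagonals chain into blocks, short diagonals are discarded", {
  catA <- mk_catalog(10, genome = "A", prefix = "a")
  catB <- mk_catalog(10, genome = "B", prefix = "b")
  diag5 <- data.frame(gene_a = sprintf("a%03d", 1:5),
                      gene_b = sprintf("b%03d", 1:5))
  bs <- chainCollinearPairs(diag5, catA, catB)
  expect_equal(nrow(blockTable(bs)), 1)
  expect_equal(blockTable(bs)$n_anchors, 5)
  diag3 <- diag5[1:3, ]
  bs3 <- chainCollinearPairs(diag3, catA, catB)
  expect_equal(nrow(blockTable(bs3)), 0)
  # antidiagonal (inverted segment) chains in '-' orientation
  anti <- data.frame(gene_a = sprintf("a%03d", 1:5),
                     gene_b = sprintf("b%03d", 5:1))
  bsa <- chainCollinearPairs(anti, catA, catB)
  expect_equal(blockTable(bsa)$orientation, "-")
  expect_equal(blockTable(bsa)$n_anchors, 5)
})

test_that("gap and length constraints hold for every emitted block", {
  set.seed(42)
  catA <- mk_catalog(80, genome = "A", prefix = "a")
  catB <- mk_catalog(80, genome = "B", prefix = "b")
  pairs <- data.frame(gene_a = sprintf("a%03d", sample(80, 60, TRUE)),
                      gene_b = sprintf("b%03d", sample(80, 60, TRUE)))
  pairs <- canonicalizePairs(pairs)
  bs <- chainCollinearPairs(pairs, catA, catB, max_gap = 8,
                            min_block_len = 3)
  an <- anchorTable(bs)
  for (b in blockTable(bs)$block_id) {
    sub <- an[an$block_id == b, ]
    expect_gte(nrow(sub), 3)
    expect_true(all(diff(sub$order_a) > 0))
    expect_true(all(diff(sub$order_b) > 0) || all(diff(sub$order_b) < 0))
    expect_true(all(abs(diff(sub$order_a)) <= 8))
    expect_true(all(abs(diff(sub$order_b)) <= 8))
  }
  # anchors of distinct blocks are disjoint
  expect_equal(anyDuplicated(an[, c("gene_a", "gene_b")]), 0)
})

test_that("chaining matches exhaustive chain enumeration on small inputs", {
  set.seed(43)
  catA <- mk_catalog(8, genome = "A", prefix = "a")
  catB <- mk_catalog(8, genome = "B", prefix = "b")
  for (rep in 1:20) {
    k <- sample(4:8, 1)
    pairs <- unique(data.frame(
      gene_a = sprintf("a%03d", sample(8, k, TRUE)),
      gene_b = sprintf("b%03d", sample(8, k, TRUE))))
    bs <- chainCollinearPairs(pairs, catA, catB, max_gap = 3,
                              min_block_len = 2)
    bt <- blockTable(bs)
    x <- as.integer(sub("a", "", pairs$gene_a)) - 1L
    y <- as.integer(sub("b", "", pairs$gene_b)) - 1L
    best <- oracle_best_chain(x, y, 3)
    if (length(best) < 2) {
      expect_equal(nrow(bt), 0)
    } else {
      expect_equal(max(bt$n_anchors), length(best))
    }
  }
})

test_that("block Ks medians follow the stated conventions", {
  catA <- mk_catalog(10, genome = "A", prefix = "a")
  catB <- mk_catalog(10, genome = "B", prefix = "b")
  mkbs <- function(n) chainCollinearPairs(
    data.frame(gene_a = sprintf("a%03d", 1:n),
               gene_b = sprintf("b%03d", 1:n)), catA, catB,
    min_block_len = 1)
  ps <- function(ks, n) data.frame(gene_a = sprintf("a%03d", 1:n),
                                   gene_b = sprintf("b%03d", 1:n), ks = ks)
  bs <- annotateBlocksKs(mkbs(3), ps(c(0.1, 0.2, 0.3), 3))
  expect_equal(blockTable(bs)$median_ks, 0.2)
  bs <- annotateBlocksKs(mkbs(1), ps(0.12, 1))
  expect_equal(blockTable(bs)$median_ks, 0.12)
  bs <- annotateBlocksKs(mkbs(2), ps(c(0.1, 0.2), 2))
  expect_equal(blockTable(bs)$median_ks, 0.15)  # midpoint convention
  # all-saturated anchors: median missing, label stays UNASSIGNED
  bs <- annotateBlocksKs(mkbs(2), ps(c(NA, NA), 2))
  expect_true(is.na(blockTable(bs)$median_ks))
  win <- data.frame(event = "SCT", lo = 0.1, hi = 0.6)
  expect_equal(blockTable(labelBlocksByEvent(bs, win))$event_label,
               "UNASSIGNED")
})

test_that("event labeling places medians into the published windows", {
  catA <- mk_catalog(10, genome = "A", prefix = "a")
  bs <- chainCollinearPairs(
    data.frame(gene_a = sprintf("a%03d", 1:4),
               gene_b = sprintf("a%03d", 5:8)), catA, catA)
  win <- data.frame(event = c("SCT", "ECH"), lo = c(0.1, 1.0),
                    hi = c(0.6, 1.6))
  lab <- function(med) {
    bt <- blockTable(bs); bt$median_ks <- med
    b2 <- methods::new("CollinearBlockSet", blocks = bt,
                       anchors = anchorTable(bs))
    blockTable(labelBlocksByEvent(b2, win))$event_label
  }
  expect_equal(lab(0.25), "SCT")   # young intra-genome peak
  expect_equal(lab(1.30), "ECH")   # old intra-genome peak
  expect_equal(lab(0.8), "UNASSIGNED")
  bad <- data.frame(event = c("SCT", "ECH"), lo = c(0.1, 0.5),
                    hi = c(0.6, 1.6))
  bt <- blockTable(bs); bt$median_ks <- 0.25
  b2 <- methods::new("CollinearBlockSet", blocks = bt,
                     anchors = anchorTable(bs))
  expect_error(labelBlocksByEvent(b2, bad), "overlap")
})

test_that("clean simulated diagonals are recovered with full recall", {
  sim <- simulateGenomePair(4, 60, duplicate_density = 0.5,
                            converted_rate = 0, sequences = FALSE,
                            seed = 44)
  bs <- chainCollinearPairs(sim$pairs, sim$catalogA, sim$catalogA)
  an <- anchorTable(bs)
  got <- paste(pmin(an$gene_a, an$gene_b), pmax(an$gene_a, an$gene_b))
  tr <- sim$truth
  wanted <- paste(pmin(tr$p1, tr$p2), pmax(tr$p1, tr$p2))
  # every implanted paralog pair on a chromosome pair with >= 4
  # duplicates is anchored in a block
  tab <- table(tr$chrom_a)
  wanted <- wanted[tr$chrom_a %in% names(tab)[tab >= 4]]
  expect_true(all(wanted %in% got))
})
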