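test_that("site profiles mirror the alignment columns exactly", {
  cds <- rep(paste(rep("GCTAAA", 20), collapse = ""), 4)
  names(cds) <- c("P1", "P2", "S1", "S2")
  q0 <- make_quartet(list(seqs = Biostrings::DNAStringSet(cds)))
  prof <- siteProfiles(q0)
  expect_true(all(vapply(prof, function(p) all(p == 0), logical(1))))
  # single mismatch between P1 and P2 at nucleotide 7
  cds2 <- cds
  substr(cds2[["P1"]], 7, 7) <- "C"  # GCT -> ... position 7 is 'A' of AAA
  q1 <- make_quartet(list(seqs = Biostrings::DNAStringSet(cds2)))
  p <- siteProfiles(q1)
  expect_equal(which(p$P1P2 == 1), 7)
  expect_equal(sum(p$P1P2, na.rm = TRUE), 1)
  # mismatch counts equal an independent recount on random quartets
  set.seed(71)
  s <- simulateQuartet(quartetSimConfig(n_codons = 100))
  q <- make_quartet(s)
  prof <- siteProfiles(q)
  ch <- lapply(as.character(alignedSeqs(q)), function(x)
    strsplit(x, "")[[1]])
  recount <- sum(ch$P1 != ch$P2)
  expect_equal(sum(prof$P1P2, na.rm = TRUE), recount)
})

test_that("score array composes ortholog and paralog profiles", {
  # paralogs match, both orthologs mismatch: +1
  expect_equal(conversionScoreArray(0L, 1L, 1L), 1)
  # paralogs mismatch, orthologs match: -1
  expect_equal(conversionScoreArray(1L, 0L, 0L), -1)
  # everything matches: 0
  expect_equal(conversionScoreArray(0L, 0L, 0L), 0)
  # one ortholog missing: missing-aware mean
  expect_equal(conversionScoreArray(0L, NA_integer_, 1L), 1)
  # all missing: 0
  expect_equal(conversionScoreArray(NA_integer_, NA_integer_, NA_integer_), 0)
})

test_that("maximal scoring segments match the trivial constructions", {
  s <- c(rep(0, 7), rep(1, 12), rep(0, 5))
  segs <- maximalScoringSegments(s, 10)
  expect_equal(nrow(segs), 1)
  expect_equal(c(segs$start, segs$end, segs$score), c(8, 19, 12))
  expect_equal(nrow(maximalScoringSegments(rep(-1, 30), 10)), 0)
  expect_equal(nrow(maximalScoringSegments(rep(0, 30), 10)), 0)
  # the min-length filter discards short positives
  expect_equal(nrow(maximalScoringSegments(c(rep(0, 10), rep(1, 5)), 10)), 0)
})

test_that("Ruzzo-Tompa equals the definitional oracle on random arrays", {
  set.seed(72)
  for (i in 1:300) {
    n <- sample(1:12, 1)
    s <- sample(c(-1, -0.5, 0, 0.5, 1), n, TRUE)
    got <- maximalScoringSegments(s, 1)
    want <- oracle_rt(s)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      m <- unname(as.matrix(got))
      expect_equal(m, unname(want), tolerance = 1e-12)
    }
  }
})

test_that("bootstrap p-values behave at the extremes and are seeded", {
  expect_equal(bootstrapSegmentP(rep(0, 100), 0, B = 1000), 1)
  s <- c(rep(-1, 200), rep(1, 30), rep(-1, 200))
  set.seed(73)
  p1 <- bootstrapSegmentP(s, 30, B = 1000)
  expect_lte(p1, 0.05)
  expect_gte(p1, 1 / 1001)
  set.seed(74); p2 <- bootstrapSegmentP(s, 30, B = 500)
  set.seed(74); p3 <- bootstrapSegmentP(s, 30, B = 500)
  expect_identical(p2, p3)
  expect_warning(bootstrapSegmentP(s, 30, B = 50), "coarse")
})

test_that("an implanted tract is called with the right direction", {
  set.seed(75)
  hits <- 0; dir_ok <- 0; n <- 25
  for (i in seq_len(n)) {
    s <- simulateQuartet(quartetSimConfig(conversion = list(
      type = "tract", start_nt = 701, end_nt = 800, acceptor = "P2",
      donor = "P1", time_fraction = 1)))
    calls <- detectPcv(make_quartet(s), genome = "A", B = 500)
    ov <- calls[calls$tract_start <= 800 & calls$tract_end >= 701, ]
    if (nrow(ov)) {
      hits <- hits + 1
      if (ov$acceptor[1] == "P2" &&
          ov$direction_confidence[1] == "resolved") dir_ok <- dir_ok + 1
    }
  }
  expect_gte(hits / n, 0.8)           # 100-nt tracts are strong signals
  expect_gte(dir_ok / max(hits, 1), 0.8)
})

test_that("recursion recovers two disjoint implanted tracts", {
  # implant the second tract manually on top of a simulated first
  set.seed(76)
  found2 <- 0
  for (i in 1:10) {
    s <- simulateQuartet(quartetSimConfig(conversion = list(
      type = "tract", start_nt = 201, end_nt = 300, acceptor = "P2",
      donor = "P1", time_fraction = 1)))
    cds <- as.character(s$seqs)
    substr(cds[["P2"]], 1001, 1100) <- substr(cds[["P1"]], 1001, 1100)
    q <- make_quartet(list(seqs = Biostrings::DNAStringSet(cds)))
    calls <- detectPcv(q, genome = "A", B = 500)
    hit1 <- any(calls$tract_start <= 300 & calls$tract_end >= 201)
    hit2 <- any(calls$tract_start <= 1100 & calls$tract_end >= 1001)
    if (hit1 && hit2) found2 <- found2 + 1
    # masking monotonicity: emitted scores never increase
    expect_true(all(diff(calls$score) <= 1e-9))
  }
  expect_gte(found2, 8)
})

test_that("tract coordinates survive the alignment round trip", {
  set.seed(77)
  s <- simulateQuartet(quartetSimConfig(conversion = list(
    type = "tract", start_nt = 301, end_nt = 400, acceptor = "P2",
    donor = "P1", time_fraction = 1)))
  cds <- as.character(s$seqs)
  # indel in S2 upstream of the tract shifts alignment columns
  cds[["S2"]] <- paste0(substr(cds[["S2"]], 1, 30),
                        substr(cds[["S2"]], 40, nchar(cds[["S2"]])))
  q <- make_quartet(list(seqs = Biostrings::DNAStringSet(cds)))
  calls <- detectPcv(q, genome = "A", B = 500)
  ov <- calls[calls$tract_start <= 400 & calls$tract_end >= 301, ]
  expect_gte(nrow(ov), 1)
  # the called span, mapped through the acceptor column map, must
  # reproduce the acceptor-coordinate tract bounds exactly
  map <- columnMaps(q)[[names(which(quartetGenes(q) == ov$acceptor[1]))]]
  span <- map[ov$aln_start[1]:ov$aln_end[1]]
  expect_equal(min(span, na.rm = TRUE), ov$tract_start[1])
  expect_equal(max(span, na.rm = TRUE), ov$tract_end[1])
})

test_that("whole-gene conversion calling follows the Ks + topology rule", {
  set.seed(78)
  # converted quartet: detected with the acceptor resolved
  s <- simulateQuartet(quartetSimConfig(conversion = list(
    type = "whole", acceptor = "P2", donor = "P1", time_fraction = 0.5)))
  q <- make_quartet(s)
  w <- detectWcv(q, genome = "A", B = 500)
  expect_equal(nrow(w), 1)
  expect_equal(w$type, "WCV")
  expect_equal(w$acceptor, "P2")
  # unconverted quartet: Ks(P1,P2) ~ 0.25 exceeds the orthologs, no call
  s0 <- simulateQuartet(quartetSimConfig(), seed = 79)
  expect_equal(nrow(detectWcv(make_quartet(s0), genome = "A", B = 200)), 0)
  # both genomes' pairs converted: both ortholog Ks elevated
  # symmetrically, so the direction cannot be polarized
  s2 <- simulateQuartet(quartetSimConfig(conversion = list(
    list(type = "whole", acceptor = "P2", donor = "P1",
         time_fraction = 0.6),
    list(type = "whole", acceptor = "S1", donor = "S2",
         time_fraction = 0.6))), seed = 80)
  w2 <- detectWcv(make_quartet(s2), genome = "A", B = 500)
  expect_equal(nrow(w2), 1)
  expect_equal(w2$direction_confidence, "both_copies")
})

test_that("status classification gives WCV precedence over PCV", {
  calls <- rbind(
    data.frame(quartet_id = "q", type = "PCV", converted_genome = "A",
               acceptor = "x", donor = "y", tract_start = 1, tract_end = 50,
               aln_start = 1, aln_end = 50, score = 5, p_value = 0.01,
               direction_confidence = "resolved"),
    data.frame(quartet_id = "q", type = "WCV", converted_genome = "A",
               acceptor = "x", donor = "y", tract_start = 1, tract_end = 300,
               aln_start = 1, aln_end = 300, score = NA, p_value = 0.001,
               direction_confidence = "resolved"))
  st <- classifyQuartet(calls)
  expect_equal(st$status[st$genome == "A"], "WCV")
  expect_equal(st$status[st$genome == "B"], "nonconverted")
  st0 <- classifyQuartet(calls[0, ], quartet_id = "q")
  expect_true(all(st0$status == "nonconverted"))
})
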