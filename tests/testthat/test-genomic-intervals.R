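test_that("consensusThreshold follows the half-the-samples rule", {
  expect_error(consensusThreshold(0), "must be")
  expect_identical(consensusThreshold(1), 1L)
  # the rule is floor(n/2) for n >= 3 but both-of-two for n = 2
  expect_identical(consensusThreshold(2), 2L)
  expect_identical(consensusThreshold(5), 2L)
})

test_that("intersectCallers keeps caller-A peaks corroborated by >=1 bp", {
  a <- PeakSet(grFromDf(data.frame(start = c(101, 500), end = c(200, 600))),
               "S1", "ERa")
  b <- PeakSet(grFromDf(data.frame(start = 200, end = 300)), "S1", "ERa")
  expect_identical(dfFromGr(peakRanges(intersectCallers(a, a))),
                   dfFromGr(peakRanges(a)))
  # single shared base at position 200 retains A's first interval only
  kept <- intersectCallers(a, b)
  expect_identical(dfFromGr(peakRanges(kept)),
                   data.frame(start = 101L, end = 200L))
  far <- PeakSet(grFromDf(data.frame(start = 5000, end = 5100)), "S1", "ERa")
  expect_length(intersectCallers(a, far), 0L)
  other <- PeakSet(peakRanges(b), "S2", "ERa")
  expect_error(intersectCallers(a, other), "same sample")
})

test_that("consensusSites merges and thresholds support", {
  one <- PeakSet(grFromDf(data.frame(start = c(10, 15, 100),
                                     end = c(20, 30, 120))), "S1", "ERa")
  cs <- consensusSites(list(one), thresholdK = 1L)
  expect_identical(dfFromGr(peakRanges(cs)),
                   data.frame(start = c(10L, 100L), end = c(30L, 120L)))
  four <- lapply(sprintf("S%d", 1:4), function(s)
    PeakSet(peakRanges(one), s, "ERa"))
  cs4 <- consensusSites(four, thresholdK = 2L)
  expect_identical(dfFromGr(peakRanges(cs4)), dfFromGr(peakRanges(cs)))
  expect_identical(siteSupport(cs4), c(4L, 4L))
  expect_error(consensusSites(list()), "at least one")
})

test_that("raising the consensus threshold never adds sites", {
  set.seed(101)
  for (rep in 1:20) {
    L <- 5000L
    ps <- lapply(1:5, function(i)
      PeakSet(grFromDf(randIntervals(sample(3:10, 1), L), L = L),
              paste0("S", i), "ERa"))
    prev <- NULL
    for (k in 1:5) {
      cur <- dfFromGr(peakRanges(consensusSites(ps, thresholdK = k)))
      if (!is.null(prev)) {
        merged <- merge(cur, prev)
        expect_identical(nrow(merged), nrow(cur))
      }
      prev <- cur
    }
  }
})

test_that("unionSites is commutative, idempotent and additive on disjoint
           sets", {
  a <- consensusSites(list(PeakSet(grFromDf(
    data.frame(start = c(10, 50), end = c(20, 60))), "S1", "ERa")), 1L)
  b <- consensusSites(list(PeakSet(grFromDf(
    data.frame(start = c(100, 200), end = c(120, 240))), "S1", "AR")), 1L)
  expect_identical(dfFromGr(peakRanges(unionSites(list(a)))),
                   dfFromGr(peakRanges(a)))
  ab <- unionSites(list(a, b)); ba <- unionSites(list(b, a))
  expect_identical(dfFromGr(peakRanges(ab)), dfFromGr(peakRanges(ba)))
  expect_identical(length(ab), length(a) + length(b))
  expect_identical(dfFromGr(peakRanges(unionSites(list(ab, ab)))),
                   dfFromGr(peakRanges(ab)))
})

test_that("overlapPartition is A-anchored and exhaustive", {
  a <- grFromDf(data.frame(start = c(10, 100, 300), end = c(20, 150, 350)))
  p <- overlapPartition(a, a)
  expect_length(p$aOnly, 0L)
  expect_length(p$shared, 3L)
  b <- grFromDf(data.frame(start = 1000, end = 1100))
  p2 <- overlapPartition(a, b)
  expect_length(p2$shared, 0L)
  expect_identical(length(p2$aOnly) + length(p2$shared), length(a))
  set.seed(7)
  for (rep in 1:25) {
    ad <- randIntervals(sample(1:8, 1), 2000L)
    bd <- randIntervals(sample(1:8, 1), 2000L)
    got <- overlapPartition(grFromDf(ad), grFromDf(bd))
    want <- bfPartition(ad, bd)
    expect_identical(length(got$aOnly), nrow(want$aOnly))
    expect_identical(length(got$shared), nrow(want$shared))
    expect_identical(length(got$bOnly), nrow(want$bOnly))
  }
})

test_that("overlapRatio endpoints and emptiness handling", {
  a <- grFromDf(data.frame(start = c(10, 100), end = c(20, 150)))
  b <- grFromDf(data.frame(start = 500, end = 600))
  expect_identical(overlapRatio(a, a), 1)
  expect_identical(overlapRatio(a, b), 0)
  expect_error(overlapRatio(GRanges(), a), "empty")
  expect_identical(overlapRatio(a, a, method = "jaccard"), 1)
})

test_that("genomicDistribution endpoints: all-promoter and all-distal", {
  genes <- grFromDf(data.frame(start = c(10000, 50000),
                               end = c(20000, 60000)))
  strand(genes) <- c("+", "-")
  mcols(genes)$gene_id <- c("g1", "g2")
  mcols(genes)$tss <- c(10000L, 60000L)
  atTss <- grFromDf(data.frame(start = c(10000, 60000),
                               end = c(10000, 60000)))
  d1 <- genomicDistribution(atTss, genes)
  expect_identical(unname(d1["promoter"]), 1)
  far <- grFromDf(data.frame(start = 200000, end = 200100))
  d2 <- genomicDistribution(far, genes)
  expect_identical(unname(d2["distal"]), 1)
  expect_equal(sum(d1), 1, tolerance = 1e-12)
})

test_that("assignTargetGenes applies the <20 kb-or-gene-body rule", {
  genes <- grFromDf(data.frame(start = 100000, end = 120000))
  strand(genes) <- "+"
  mcols(genes)$gene_id <- "g1"
  inside <- grFromDf(data.frame(start = 110000, end = 110300))
  hit <- assignTargetGenes(inside, genes)
  expect_identical(hit$gene_id, "g1")
  expect_identical(hit$distance, 0L)
  # gene body ends at 120000; a site starting 25 kb past it is unassigned
  at25k <- grFromDf(data.frame(start = 145001, end = 145300))
  expect_identical(nrow(assignTargetGenes(at25k, genes)), 0L)
  # boundary: gap of 19999 is in, gap of 20000 is out
  gap19999 <- grFromDf(data.frame(start = 140000, end = 140300))
  expect_identical(assignTargetGenes(gap19999, genes)$distance, 19999L)
  gap20000 <- grFromDf(data.frame(start = 140001, end = 140300))
  expect_identical(nrow(assignTargetGenes(gap20000, genes)), 0L)
})

test_that("windowMatrix centers, clips and preserves width", {
  L <- 1e6L
  site <- grFromDf(data.frame(start = 1001, end = 2000), L = L)
  w <- windowMatrix(site, 5000L)
  # BED center 1500 -> BED window [-3500, 6500) clipped to [0, 6500)
  expect_identical(end(w), 6500L)
  expect_identical(start(w), 1L)
  mid <- grFromDf(data.frame(start = 500001, end = 500200), L = L)
  wm <- windowMatrix(mid, 5000L)
  expect_identical(end(wm) - (start(wm) - 1L), 10000L)
  nearEnd <- grFromDf(data.frame(start = L - 100L, end = L), L = L)
  expect_identical(end(windowMatrix(nearEnd, 5000L)), L)
})
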