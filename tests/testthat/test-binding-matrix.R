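test_that("countInSites counts fragment midpoints once each", {
  sites <- grFromDf(data.frame(start = c(100, 500), end = c(200, 700)))
  expect_identical(countInSites(GRanges(), sites), c(0L, 0L))
  frag <- grFromDf(data.frame(start = c(120, 140, 160), end = c(170, 190,
                                                                210)))
  expect_identical(sum(countInSites(frag, sites)), 3L)
  overlapping <- grFromDf(data.frame(start = c(100, 150), end = c(200,
                                                                  250)))
  expect_error(countInSites(frag, overlapping), "overlap")
  # brute-force midpoint membership and permutation invariance
  set.seed(21)
  for (rep in 1:10) {
    fr <- randIntervals(30, 2000L, maxWidth = 50L)
    st <- bfUnion(list(randIntervals(5, 2000L)), 2000L)
    got <- countInSites(grFromDf(fr), grFromDf(st))
    mid <- fr$start + (fr$end - fr$start) %/% 2L
    want <- vapply(seq_len(nrow(st)), function(i)
      sum(mid >= st$start[i] & mid <= st$end[i]), integer(1))
    expect_identical(got, want)
    perm <- sample(nrow(fr))
    expect_identical(countInSites(grFromDf(fr[perm, ]), grFromDf(st)), got)
  }
})

test_that("normalizeCounts equalizes column totals then logs", {
  m <- matrix(c(2, 6, 4, 4, 8, 0), 3, 2,
              dimnames = list(paste0("s", 1:3), c("a", "b")))
  norm <- normalizeCounts(m)
  expect_equal(norm, log2(m + 1))  # equal totals: pure log2(x+1)
  m2 <- cbind(m, c = m[, "a"] * 2)
  norm2 <- normalizeCounts(m2)
  expect_equal(norm2[, "c"], norm2[, "a"])  # scale invariance
  set.seed(5)
  r <- matrix(rpois(60, 30), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("x", 1:6)))
  scaled <- 2^normalizeCounts(r) - 1
  expect_equal(diff(range(colSums(scaled))), 0, tolerance = 1e-9)
  z <- cbind(r, zero = 0)
  expect_warning(normalizeCounts(z), "all-zero")
})

test_that("correlationMatrix matches the Pearson formula and flags
           degenerate samples", {
  m <- matrix(c(1, 2, 3, 2, 4, 6.5, 5, 1, 0, 1, 2, 3), 3, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  r <- correlationMatrix(m)
  pearson <- function(x, y)
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r["a", "b"], pearson(m[, "a"], m[, "b"]))
  expect_equal(r["a", "d"], 1)          # duplicated sample
  expect_equal(unname(diag(r)), rep(1, 4))
  neg <- cbind(m, e = -m[, "a"])
  expect_equal(correlationMatrix(neg)["a", "e"], -1)
  expect_equal(r, t(r))
  expect_gte(min(eigen(r, symmetric = TRUE)$values), -1e-8)
  flat <- cbind(m, f = c(2, 2, 2))
  expect_error(correlationMatrix(flat), "f")
})

test_that("hierarchicalCluster co-clusters duplicates deterministically", {
  set.seed(3)
  base <- matrix(rnorm(40), 10, 4)
  m <- cbind(base[, c(1, 1, 2, 2)] + matrix(rnorm(40, sd = 1e-3), 10, 4))
  colnames(m) <- c("a1", "a2", "b1", "b2")
  r <- correlationMatrix(m)
  cl <- hierarchicalCluster(r, 2L)
  expect_identical(cl$labels[["a1"]], cl$labels[["a2"]])
  expect_identical(cl$labels[["b1"]], cl$labels[["b2"]])
  expect_false(cl$labels[["a1"]] == cl$labels[["b1"]])
  expect_error(hierarchicalCluster(r, 5L), "exceeds")
})

test_that("shared-module architecture yields within-patient ERa-AR
           correlation above between-patient same-factor", {
  cfg <- cohortConfig(
    nPatients = 8L, factors = c("ERa", "AR"),
    nSamplesPerFactor = c(ERa = 8L, AR = 8L),
    genomeLength = 2e6, nGenes = 60L,
    coBindingModules = list(
      shared = list(factors = c("ERa", "AR"), n = 300L,
                    promoterBias = 0.1, presenceRate = 0.8)),
    fracDifferentialSites = 0, nSignatureGenes = 0L, seed = 404L)
  wins <- vapply(1:10, function(s) {
    coh <- simulateCohort(cfg, seed = 404L + s)
    se <- normalizeCounts(coh$siteCounts)
    r <- correlationMatrix(assay(se, "normalized"))
    cd <- colData(se)
    within <- mean(vapply(unique(cd$patient), function(p) {
      ids <- rownames(cd)[cd$patient == p]
      r[ids[1], ids[2]]
    }, numeric(1)))
    eraIds <- rownames(cd)[cd$factor == "ERa"]
    between <- mean(r[eraIds, eraIds][upper.tri(diag(length(eraIds)))])
    within > between
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})
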