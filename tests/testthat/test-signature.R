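test_that("full shrinkage gives zero coefficients and prevalence
           intercept", {
  set.seed(51)
  x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("g", 1:6)))
  y <- rep(c(0, 1, 1, 1), 10)  # prevalence 0.75
  m <- fitElasticNet(x, y, alpha = 0.5, lambda = c(1e6, 5e5))
  expect_true(all(coef(m) == 0))
  expect_equal(m@intercept, qlogis(0.75), tolerance = 1e-6)
  expect_error(fitElasticNet(x, y, lambda = 1), "degenerate")
  expect_error(fitElasticNet(x, rep(1, 40)), "both classes")
})

test_that("scoreSamples is the linear predictor and refuses missing
           genes", {
  m <- new("SignatureModel", geneIds = c("gA", "gB"),
           coefficients = c(gA = 2, gB = -1), intercept = 0.5,
           alpha = 0.5, lambda = 0.1, metadata = list())
  x <- matrix(c(1, 0, 3, 2, 1, -1), 3, 2,
              dimnames = list(paste0("s", 1:3), c("gA", "gB")))
  expect_equal(unname(scoreSamples(m, x)),
               unname(0.5 + 2 * x[, "gA"] - x[, "gB"]))
  expect_equal(scoreSamples(m, x[c(1, 1), ])[1],
               scoreSamples(m, x[c(1, 1), ])[2])
  expect_error(scoreSamples(m, x[, "gA", drop = FALSE]), "gB")
})

test_that("rocAuc equals the all-pairs statistic and is rank
           invariant", {
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  y <- c(1, 1, 0, 1, 0, 0)
  pairsAuc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b)
      ifelse(a > b, 1, ifelse(a == b, 0.5, 0))))
  }
  expect_equal(rocAuc(s, y)$auc, pairsAuc(s, y))
  expect_equal(rocAuc(c(2, 3, 0, 1), c(1, 1, 0, 0))$auc, 1)
  # ties get half credit
  st <- c(1, 1, 0); yt <- c(1, 0, 0)
  expect_equal(rocAuc(st, yt)$auc, pairsAuc(st, yt))
  # invariance under strictly monotone transforms
  set.seed(52)
  sc <- rnorm(50); yy <- rbinom(50, 1, 0.4)
  expect_equal(rocAuc(exp(sc), yy)$auc, rocAuc(sc, yy)$auc)
  expect_error(rocAuc(sc, rep(1, 50)), "both classes")
})

test_that("rocAuc agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  sc <- rnorm(80); yy <- rbinom(80, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(yy, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rocAuc(sc, yy)$auc, ref, tolerance = 1e-12)
})

test_that("medianRiskSplit halves the cohort", {
  expect_identical(unname(medianRiskSplit(1:4)),
                   c("low", "low", "high", "high"))
  expect_identical(unname(medianRiskSplit(rep(2, 5))), rep("low", 5))
  odd <- medianRiskSplit(c(5, 1, 4, 2, 3))
  expect_identical(sum(odd == "high"), 2L)
  expect_identical(sum(odd == "low"), 3L)
  expect_error(medianRiskSplit(1), "at least 2")
})

test_that("bootstrapNull is seeded-deterministic with smoothed one-tailed
           p", {
  set.seed(54)
  d <- plantedExpression(30, 25, paste0("sig", 1:5), shift = 0)
  v <- plantedExpression(30, 25, paste0("sig", 1:5), shift = 0)
  args <- list(d$x, d$y, v$x, v$y, geneUniverse = d$genes, setSize = 5,
               B = 20, seed = 99, nfolds = 5, nlambda = 20,
               aucObserved = 0)
  b1 <- do.call(bootstrapNull, args)
  b2 <- do.call(bootstrapNull, args)
  expect_identical(b1$nullAuc, b2$nullAuc)
  expect_length(b1$nullAuc, 20L)
  # observed at the floor: every null draw >= 0, so p is exactly 1
  expect_identical(b1$p, 1)
  expect_gt(b1$p, 0)
})

test_that("compareFeatureSets is reproducible and validates inputs", {
  set.seed(55)
  d <- plantedExpression(30, 20, paste0("sig", 1:5), shift = 1.2)
  v <- plantedExpression(30, 20, paste0("sig", 1:5), shift = 1.2)
  r <- compareFeatureSets(d$x, d$y, v$x, v$y,
                          list(one = d$genes[1:10], two = d$genes[1:10]),
                          nfolds = 5, seed = 7)
  expect_identical(r$one$roc$auc, r$two$roc$auc)
  expect_error(compareFeatureSets(d$x, d$y, v$x, v$y,
                                  list(bad = character())), "non-empty")
})
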