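smallConfig <- function(...) {
  defaults <- list(
    nPatients = 10L, factors = c("ERa", "FOXA1"),
    nSamplesPerFactor = c(ERa = 10L, FOXA1 = 6L),
    genomeLength = 2e6, nGenes = 80L,
    coBindingModules = list(
      shared = list(factors = c("ERa", "FOXA1"), n = 150L,
                    promoterBias = 0.2, presenceRate = 0.8),
      eraOnly = list(factors = "ERa", n = 50L,
                     promoterBias = 0.6, presenceRate = 0.7)),
    nSignatureGenes = 8L, seed = 202L)
  do.call(cohortConfig, utils::modifyList(defaults, list(...)))
}

test_that("cohortConfig validates its fields", {
  expect_error(cohortConfig(factors = character(),
                            nSamplesPerFactor = integer()), "non-empty")
  expect_error(smallConfig(fracDifferentialSites = 1.4), "\\[0, 1\\]")
  expect_error(smallConfig(lnPositiveRate = -0.1), "\\[0, 1\\]")
  expect_error(cohortConfig(nPatients = 5L), "more samples than patients")
})

test_that("generateGeneAnnotation packs disjoint genes deterministically", {
  cfg <- smallConfig()
  empty <- generateGeneAnnotation(cohortConfig(nGenes = 0L, seed = 1L))
  expect_length(empty, 0L)
  ann <- generateGeneAnnotation(cfg)
  expect_length(ann, 80L)
  expect_length(reduce(ann, ignore.strand = TRUE), 80L)  # pairwise disjoint
  expect_true(all(start(ann) >= 1 & end(ann) <= cfg$genomeLength))
  expect_identical(ann, generateGeneAnnotation(cfg))
  expect_error(generateGeneAnnotation(
    cohortConfig(nGenes = 2000L, genomeLength = 1e6, seed = 1L)),
    "infeasible packing")
})

test_that("presence rates 1 and 0 are degenerate as specified", {
  cfg <- smallConfig()
  cfg$coBindingModules$shared$presenceRate <- 1
  cfg$coBindingModules$eraOnly$presenceRate <- 0
  ann <- generateGeneAnnotation(cfg)
  ls <- generatePeakLandscape(cfg, ann)
  mod <- mcols(ls$masterSites)$module
  expect_true(all(ls$presence[mod == "shared", ]))
  eraSamples <- ls$sampleTable$sample_id[ls$sampleTable$factor == "ERa"]
  # differential sites are forced present; rate 0 empties the rest
  nonDiff <- mod == "eraOnly" & !mcols(ls$masterSites)$differential
  expect_false(any(ls$presence[nonDiff, eraSamples]))
})

test_that("emitted peaks live inside the genome and regenerate
           identically", {
  cfg <- smallConfig()
  coh <- simulateCohort(cfg)
  for (ps in coh$landscape$peakSets) {
    gr <- peakRanges(ps)
    expect_true(all(start(gr) >= 1 & end(gr) <= cfg$genomeLength))
  }
  coh2 <- simulateCohort(cfg)
  expect_identical(assay(coh$siteCounts, "counts"),
                   assay(coh2$siteCounts, "counts"))
  expect_identical(coh$clinical, coh2$clinical)
  expect_identical(dfFromGr(coh$annotation), dfFromGr(coh2$annotation))
})

test_that("counts concentrate on the bound mean when dispersion vanishes
           and scale with depth", {
  cfg <- smallConfig(countDispersion = 1e6, backgroundMean = 0,
                     patientEffectSd = 0)
  ann <- generateGeneAnnotation(cfg)
  ls <- generatePeakLandscape(cfg, ann)
  ln <- setNames(rep("neg", 10), sprintf("P%02d", 1:10))
  se <- generateCounts(ls, cfg, ln, depths = rep(1, 16))
  m <- assay(se, "counts")
  bound <- as.vector(ls$presence)
  cnt <- as.vector(m)[bound]
  seBound <- sqrt(cfg$boundMean / length(cnt))  # ~Poisson at tiny dispersion
  expect_lt(abs(mean(cnt) - cfg$boundMean), 3 * seBound)
  expect_true(all(as.vector(m)[!bound] == 0))
  zeroDepth <- generateCounts(ls, cfg, ln, depths = rep(0, 16))
  expect_true(all(assay(zeroDepth, "counts") == 0))
})

test_that("ground truth is internally consistent", {
  coh <- simulateCohort(smallConfig())
  gt <- coh$groundTruth
  master <- coh$landscape$masterSites
  expect_true(all(gt$differentialSiteIds %in% mcols(master)$site_id))
  expect_true(all(gt$signatureGeneIds %in%
                  mcols(coh$annotation)$gene_id))
  # every signature gene is proximal to >= 1 differential site
  diffGr <- master[mcols(master)$site_id %in% gt$differentialSiteIds]
  prox <- assignTargetGenes(diffGr, coh$annotation, 20000L)
  expect_true(all(gt$signatureGeneIds %in% prox$gene_id))
  expect_error(simulateCohort(smallConfig(nGenes = 0L)),
               "no gene is proximal")
})

test_that("censoring and hazard behave as configured", {
  cfg <- smallConfig(censoringRate = 0)
  coh <- simulateCohort(cfg)
  expect_true(all(coh$clinical$os_event == 1))
  expect_true(all(coh$clinical$dmfs_event == 1))
  # gamma = 0: survival is independent of the planted risk groups
  cfg0 <- smallConfig(hazardCoefficient = 0, nPatients = 40L,
                      nSamplesPerFactor = c(ERa = 10L, FOXA1 = 6L))
  pvals <- vapply(1:20, function(s) {
    coh <- simulateCohort(cfg0, seed = 300L + s)
    grp <- ifelse(coh$groundTruth$trueRisk >
                  median(coh$groundTruth$trueRisk), "high", "low")
    logrankTest(coh$clinical$os_time, coh$clinical$os_event, grp)$p
  }, numeric(1))
  expect_lte(sum(pvals < 0.05), 4L)  # about nominal over 20 nulls
})

test_that("cohort pairs share the genome and the planted signature", {
  cfg <- smallConfig()
  pair <- simulateCohortPair(cfg, nValidationPatients = 12L)
  expect_identical(dfFromGr(pair$discovery$annotation),
                   dfFromGr(pair$validation$annotation))
  expect_identical(pair$discovery$groundTruth$signatureGeneIds,
                   pair$validation$groundTruth$signatureGeneIds)
  expect_false(identical(assay(pair$discovery$expression),
                         assay(pair$validation$expression)[, 1:10]))
  expect_identical(ncol(pair$validation$expression), 12L)
})

test_that("writeCohort round-trips peaks, matrices and clinical", {
  coh <- simulateCohort(smallConfig())
  dir <- withr::local_tempdir()
  writeCohort(coh, dir)
  ps <- coh$landscape$peakSets[[1]]
  back <- readPeakBed(file.path(dir, "peaks",
                                paste0(sampleId(ps), ".bed")),
                      sampleId(ps), factorName(ps))
  expect_identical(dfFromGr(peakRanges(back)), dfFromGr(peakRanges(ps)))
  cnt <- readMatrixTsv(file.path(dir, "site_counts.tsv"))
  expect_identical(unname(cnt), unname(assay(coh$siteCounts, "counts")))
  ann <- readGeneAnnotation(file.path(dir, "annotation.bed"))
  expect_identical(dfFromGr(ann), dfFromGr(coh$annotation))
  cl <- read.delim(file.path(dir, "clinical.tsv"))
  expect_identical(cl$ln_status, coh$clinical$ln_status)
})
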