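#' @include synthetic.R differential.R expression.R survival.R knn.R
#' @importFrom tools md5sum
NULL

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full discovery/validation analysis
#'
#' Simulates a discovery/validation cohort pair from \code{config}, then
#' executes the complete analysis: per-factor consensus sites; lymph-node
#' differential ERa and FOXA1 binding (per-site test, p < 0.01); proximal
#' target genes (<20 kb or gene body); three elastic-net signatures (ERa
#' targets, FOXA1 targets, union) trained on discovery expression with
#' leave-one-out cross-validation and scored on the validation cohort
#' (ROC/AUC); a size-matched random-gene-set bootstrap null for the union
#' signature; a median risk split of validation scores followed by DMFS
#' log-rank and multivariate Cox (risk group, LN-status, endocrine therapy,
#' chemotherapy, radiotherapy, age); and a cross-cohort k-NN transfer of
#' LN-status in ERa binding-count space. All artifacts are written under
#' \code{outDir} and summarized in a machine-readable run report with md5
#' checksums.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param outDir output directory.
#' @param nValidationPatients validation cohort size (default 66).
#' @param pThreshold p-value cutoff for clinical-group differential binding
#'   (default 0.01).
#' @param maxDistance target-gene distance rule in bp (default 20000).
#' @param alpha elastic-net mixing (default 0.5).
#' @param B bootstrap replicates (default 1000).
#' @param bootstrapNfolds CV folds inside bootstrap replicates (NULL =
#'   leave-one-out, like the observed model).
#' @param k,minkowskiOrder k-NN parameters (defaults 5 and 2).
#' @param seed root seed; all stages derive their streams from it.
#' @return the run report (list), invisibly also written as
#'   \code{report.json}.
#' @export
runDiscoveryValidation <- function(config, outDir,
                                   nValidationPatients = 66L,
                                   pThreshold = 0.01,
                                   maxDistance = 20000L, alpha = 0.5,
                                   B = 1000L, bootstrapNfolds = NULL,
                                   k = 5L, minkowskiOrder = 2,
                                   seed = config$seed) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  pair <- .stage("simulate", simulateCohortPair(
    config, nValidationPatients = nValidationPatients, seed = seed))
  disc <- pair$discovery; valid <- pair$validation

  consensus <- .stage("consensus", {
    byFactor <- split(disc$landscape$peakSets,
                      disc$landscape$sampleTable$factor)
    lapply(byFactor, consensusSites)
  })
  consensusCounts <- vapply(consensus, length, integer(1))

  diffBind <- .stage("differential", {
    se <- normalizeCounts(disc$siteCounts)
    out <- lapply(c(ERa = "ERa", FOXA1 = "FOXA1"), function(f) {
      sub <- se[, colData(se)$factor == f]
      differentialSites(sub, colData(sub)$ln_status, mode = "pvalue",
                        threshold = pThreshold)
    })
    out
  })
  sigSites <- lapply(diffBind, function(d) d$site_id[d$significant])

  targets <- .stage("targets", {
    master <- disc$landscape$masterSites
    lapply(sigSites, function(ids) {
      gr <- master[match(ids, mcols(master)$site_id)]
      sort(unique(assignTargetGenes(gr, disc$annotation,
                                    maxDistance)$gene_id))
    })
  })
  geneSets <- list(ERa = targets$ERa, FOXA1 = targets$FOXA1,
                   union = sort(union(targets$ERa, targets$FOXA1)))

  expr <- .stage("expression", {
    prep <- function(cohort) {
      f <- filterSamples(cohort$expression, rule = "total")
      f <- normalizeLog(f)
      x <- t(assay(f, "normalized"))
      y <- as.integer(colData(f)$ln_status == "pos")
      list(x = x, y = y, ids = rownames(x))
    }
    list(disc = prep(disc), valid = prep(valid))
  })

  signatures <- .stage("signature", {
    if (length(geneSets$union) == 0L)
      stop("no target genes survive the differential-binding stage")
    compareFeatureSets(expr$disc$x, expr$disc$y, expr$valid$x,
                       expr$valid$y, geneSets, alpha = alpha,
                       seed = seed + 1L)
  })
  aucs <- vapply(signatures, function(s) s$roc$auc, numeric(1))

  boot <- .stage("bootstrap", bootstrapNull(
    expr$disc$x, expr$disc$y, expr$valid$x, expr$valid$y,
    geneUniverse = colnames(expr$disc$x),
    setSize = length(geneSets$union), B = B, seed = seed + 2L,
    alpha = alpha, nfolds = bootstrapNfolds,
    aucObserved = aucs[["union"]]))

  surv <- .stage("survival", {
    scores <- scoreSamples(signatures$union$model,
                           expr$valid$x[, geneSets$union, drop = FALSE])
    riskGroup <- medianRiskSplit(scores)
    cl <- valid$clinical[match(expr$valid$ids, valid$clinical$sample_id), ]
    cl$risk_high <- as.integer(riskGroup == "high")
    lr <- logrankTest(cl$dmfs_time, cl$dmfs_event, riskGroup)
    cl$ln_pos <- as.integer(cl$ln_status == "pos")
    cox <- coxFit(cl, c("risk_high", "ln_pos", "endocrine", "chemo",
                        "radio", "age"),
                  timeCol = "dmfs_time", eventCol = "dmfs_event")
    km <- kmEstimate(cl$dmfs_time, cl$dmfs_event, riskGroup)
    list(scores = scores, riskGroup = riskGroup, logrank = lr, cox = cox,
         km = km)
  })

  knn <- .stage("knn", {
    if (length(sigSites$ERa) < 1L) stop("no differential ERa sites")
    normCounts <- function(cohort) {
      se <- normalizeCounts(cohort$siteCounts)
      sub <- se[sigSites$ERa, colData(se)$factor == "ERa"]
      list(x = t(assay(sub, "normalized")),
           ln = colData(sub)$ln_status)
    }
    tr <- normCounts(disc); te <- normCounts(valid)
    pred <- knnPredict(tr$x, tr$ln, te$x, k = k, p = minkowskiOrder)
    list(predictions = pred, accuracy = mean(pred == te$ln))
  })

  files <- .stage("write", {
    for (f in names(diffBind))
      utils::write.table(diffBind[[f]],
                         file.path(outDir, paste0("differential_", f,
                                                  ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(genes = signatures$union$model@geneIds,
           coefficients = unname(coef(signatures$union$model)),
           intercept = signatures$union$model@intercept,
           alpha = alpha, lambda = signatures$union$model@lambda,
           seed = seed),
      file.path(outDir, "signature_union.json"), auto_unbox = TRUE,
      digits = NA)
    utils::write.table(
      data.frame(sample_id = expr$valid$ids, score = surv$scores,
                 risk_group = surv$riskGroup),
      file.path(outDir, "validation_scores.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(replicate = seq_len(B),
                                  auc = boot$nullAuc),
                       file.path(outDir, "bootstrap_null.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(surv$km, file.path(outDir, "km_dmfs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sort(list.files(outDir, recursive = TRUE, full.names = FALSE))
  })
  files <- setdiff(files, "report.json")
  checksums <- stats::setNames(
    unname(md5sum(file.path(outDir, files))), files)

  report <- list(
    config = config[c("nPatients", "nGenes", "genomeLength",
                      "fracDifferentialSites", "differentialFold",
                      "nSignatureGenes", "hazardCoefficient", "seed")],
    parameters = list(nValidationPatients = nValidationPatients,
                      pThreshold = pThreshold, maxDistance = maxDistance,
                      alpha = alpha, B = B, k = k,
                      minkowskiOrder = minkowskiOrder, seed = seed),
    stages = list(
      consensus = list(sitesPerFactor = as.list(consensusCounts)),
      differential = list(
        nSignificant = lapply(sigSites, length)),
      targets = list(nGenes = lapply(geneSets, length)),
      signature = list(
        auc = as.list(aucs),
        nContributing = sum(coef(signatures$union$model) != 0)),
      bootstrap = list(p = boot$p, B = B,
                       aucObserved = boot$aucObserved),
      survival = list(logrank_chisq = surv$logrank$chisq,
                      logrank_p = surv$logrank$p,
                      cox_signature_p = surv$cox$coefficients$p[
                        surv$cox$coefficients$term == "risk_high"],
                      cox_converged = surv$cox$converged),
      knn = list(accuracy = knn$accuracy)),
    checksums = as.list(checksums),
    version = as.character(utils::packageVersion("cistroSig")))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
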