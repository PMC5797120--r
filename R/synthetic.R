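#' @include genomic-intervals.R binding-matrix.R signature.R
NULL

#' Configuration of a synthetic tumor cohort
#'
#' Defines every parameter of the generator: the profiled factors and how
#' many tumors each was assayed in (the study design: 30 ERa, 10 AR, 7 GR,
#' 4 PR, 7 FOXA1, 3 GATA3, plus the H3K4me1 enhancer mark), the co-binding
#' architecture (a shared steroid-hormone-receptor module, an
#' ERa/FOXA1/GATA3 enhancer module, a promoter-enriched ERa-only module,
#' FOXA1-selective and factor-private modules), lymph-node-linked
#' differential binding, negative-binomial count noise, prognostic
#' target-gene expression and censored survival. All downstream analyses
#' are exercised against cohorts drawn from this configuration.
#'
#' @param nPatients patients in the cohort (expression + clinical).
#' @param factors factor names.
#' @param nSamplesPerFactor named integer, ChIP samples per factor (each
#'   factor is profiled in the first n patients).
#' @param genomeLength single linear chromosome length in bp.
#' @param chrom chromosome name.
#' @param nGenes genes to pack into the genome.
#' @param geneLengthRange min/max gene length in bp.
#' @param coBindingModules list of modules, each
#'   \code{list(factors=, n=, promoterBias=, presenceRate=)}.
#' @param fracDifferentialSites fraction of ERa/FOXA1 master sites whose
#'   binding strength is lymph-node linked.
#' @param differentialFold mean fold change at differential sites.
#' @param nSignatureGenes prognostic genes planted among the targets of
#'   differential sites.
#' @param expressionFold expression fold change of signature genes between
#'   LN groups.
#' @param countDispersion,expressionDispersion negative-binomial size
#'   parameters (shared across sites / genes).
#' @param boundMean,backgroundMean expected fragment counts at bound /
#'   unbound sites at unit depth.
#' @param patientEffectSd sd (log scale) of the patient-by-site binding
#'   effect shared across factors (drives within-patient correlation).
#' @param baselineExprMeanLog,baselineExprSdLog log-normal parameters of
#'   per-gene baseline expression means.
#' @param peakWidthRange emitted peak width range in bp.
#' @param peakJitter max absolute jitter of a peak center around its master
#'   site, bp.
#' @param promoterWindow promoter half-width around the TSS, bp.
#' @param lnPositiveRate probability a patient is lymph-node positive.
#' @param censoringRate approximate fraction of censored records.
#' @param hazardCoefficient gamma: log-hazard per unit of standardized risk.
#' @param baselineHazard exponential baseline hazard (per month).
#' @param seed root seed for the cohort.
#' @return object of class \code{CohortConfig} (validated list).
#' @export
cohortConfig <- function(
    nPatients = 46L,
    factors = c("ERa", "AR", "GR", "PR", "FOXA1", "GATA3", "H3K4me1"),
    nSamplesPerFactor = c(ERa = 30L, AR = 10L, GR = 7L, PR = 4L,
                          FOXA1 = 7L, GATA3 = 3L, H3K4me1 = 7L),
    genomeLength = 5e7, chrom = "chr1",
    nGenes = 2000L, geneLengthRange = c(5000L, 20000L),
    coBindingModules = list(
      sharedSHR = list(factors = c("ERa", "AR", "GR", "PR"), n = 1200L,
                       promoterBias = 0.1, presenceRate = 0.8),
      enhancerERaFOXA1 = list(factors = c("ERa", "FOXA1", "GATA3",
                                          "H3K4me1"), n = 600L,
                              promoterBias = 0.1, presenceRate = 0.7),
      promoterERaOnly = list(factors = "ERa", n = 500L,
                             promoterBias = 0.7, presenceRate = 0.7),
      foxa1Selective = list(factors = c("FOXA1", "H3K4me1"), n = 400L,
                            promoterBias = 0.05, presenceRate = 0.7),
      prSelective = list(factors = "PR", n = 150L,
                         promoterBias = 0.1, presenceRate = 0.7),
      gata3Private = list(factors = "GATA3", n = 150L,
                          promoterBias = 0.2, presenceRate = 0.6)),
    fracDifferentialSites = 0.1, differentialFold = 3,
    nSignatureGenes = 20L, expressionFold = 1.5,
    countDispersion = 8, expressionDispersion = 6,
    boundMean = 100, backgroundMean = 5, patientEffectSd = 0.5,
    baselineExprMeanLog = log(200), baselineExprSdLog = 1,
    peakWidthRange = c(200L, 600L), peakJitter = 100L,
    promoterWindow = 3000L, lnPositiveRate = 0.5,
    censoringRate = 0.3, hazardCoefficient = 1,
    baselineHazard = log(2) / 60, seed = 1L) {
  cfg <- as.list(environment())
  if (length(cfg$factors) == 0L) stop("factors must be non-empty")
  if (!all(names(cfg$nSamplesPerFactor) %in% cfg$factors) ||
      !all(cfg$factors %in% names(cfg$nSamplesPerFactor)))
    stop("nSamplesPerFactor must be named by the factors")
  num <- c(cfg$nSamplesPerFactor, cfg$nPatients, cfg$genomeLength,
           cfg$nGenes, cfg$nSignatureGenes, cfg$countDispersion,
           cfg$expressionDispersion, cfg$boundMean, cfg$backgroundMean,
           cfg$censoringRate, cfg$baselineHazard)
  if (any(num < 0)) stop("counts, rates and dispersions must be >= 0")
  frac <- c(cfg$fracDifferentialSites, cfg$lnPositiveRate,
            cfg$censoringRate,
            vapply(cfg$coBindingModules, function(m)
              c(m$promoterBias, m$presenceRate), numeric(2)))
  if (any(frac < 0 | frac > 1)) stop("fractions must lie in [0, 1]")
  for (m in cfg$coBindingModules)
    if (!all(m$factors %in% cfg$factors))
      stop("module factors must be a subset of the configured factors")
  if (any(cfg$nSamplesPerFactor > cfg$nPatients))
    stop("a factor cannot be profiled in more samples than patients")
  structure(cfg, class = "CohortConfig")
}

.patientIds <- function(n) sprintf("P%02d", seq_len(n))

#' Generate a non-overlapping gene annotation
#'
#' Packs \code{nGenes} disjoint genes of random length into the genome with
#' random strand; the leftover space is distributed as random intergenic
#' gaps. Errors if the genes cannot fit.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param seed RNG seed (default: the config's).
#' @return sorted gene \code{GRanges} with \code{gene_id} and \code{tss}
#'   columns and \code{seqlengths} set.
#' @export
generateGeneAnnotation <- function(config, seed = config$seed) {
  .withSeed(seed, {
    nG <- config$nGenes
    gl <- config$genomeLength
    if (nG == 0L) {
      gr <- GRanges()
      mcols(gr)$gene_id <- character(0)
      mcols(gr)$tss <- integer(0)
      return(gr)
    }
    len <- round(stats::runif(nG, config$geneLengthRange[1L],
                              config$geneLengthRange[2L]))
    free <- gl - sum(len)
    if (free < nG + 1L)
      stop("infeasible packing: ", nG, " genes of mean length ",
           round(mean(len)), " bp do not fit in ", gl,
           " bp; reduce nGenes or gene lengths")
    gaps <- floor(diff(c(0, sort(stats::runif(nG)), 1)) * free)
    starts <- cumsum(gaps[seq_len(nG)]) + cumsum(c(0, len[-nG])) + 1L
    strand <- sample(c("+", "-"), nG, replace = TRUE)
    gr <- GRanges(config$chrom, IRanges(starts, width = len),
                  strand = strand)
    seqlengths(gr) <- stats::setNames(as.integer(gl), config$chrom)
    mcols(gr)$gene_id <- sprintf("g%04d", seq_len(nG))
    mcols(gr)$tss <- ifelse(strand == "-", end(gr), start(gr))
    sort(gr, ignore.strand = TRUE)
  })
}

#' Generate the master-site peak landscape
#'
#' Lays out master binding sites module by module (promoter-biased modules
#' place a site near a random TSS with probability \code{promoterBias}),
#' flags a fraction of ERa/FOXA1 sites as lymph-node differential, and for
#' every (factor, sample) draws site presence as Bernoulli(module presence
#' rate), emitting each present site as a jittered peak of random width.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param annotation gene \code{GRanges} from
#'   \code{\link{generateGeneAnnotation}}.
#' @param seed RNG seed.
#' @param masterSites optional precomputed master-site \code{GRanges}; when
#'   given (e.g. for a validation cohort sharing the discovery genome) only
#'   presence and peaks are drawn.
#' @return list: \code{masterSites} (GRanges, width-300 intervals with
#'   site_id, module, differential, diffDirection), \code{peakSets} (named
#'   list of \linkS4class{PeakSet}, one per factor-sample), \code{presence}
#'   (logical sites-by-samples matrix), \code{sampleTable} (data.frame
#'   sample_id, patient, factor).
#' @export
generatePeakLandscape <- function(config, annotation, seed = config$seed,
                                  masterSites = NULL) {
  .withSeed(seed, {
    gl <- config$genomeLength
    mods <- config$coBindingModules
    if (is.null(masterSites)) {
      centers <- integer(0); modLab <- character(0)
      for (nm in names(mods)) {
        m <- mods[[nm]]
        if (m$n == 0L) next
        usePromoter <- stats::runif(m$n) < m$promoterBias
        cen <- integer(m$n)
        nP <- sum(usePromoter)
        if (nP > 0L && length(annotation) > 0L) {
          tss <- mcols(annotation)$tss[sample.int(length(annotation), nP,
                                                  replace = TRUE)]
          cen[usePromoter] <- tss + round(stats::runif(
            nP, -config$promoterWindow, config$promoterWindow))
        } else usePromoter[] <- FALSE
        cen[!usePromoter] <- round(stats::runif(sum(!usePromoter), 1, gl))
        centers <- c(centers, pmin(pmax(cen, 400L), gl - 400L))
        modLab <- c(modLab, rep(nm, m$n))
      }
      nSites <- length(centers)
      master <- GRanges(config$chrom,
                        IRanges(centers - 150L, centers + 149L))
      seqlengths(master) <- stats::setNames(as.integer(gl), config$chrom)
      mcols(master)$site_id <- siteIds(master)
      mcols(master)$module <- modLab
      mcols(master)$center <- centers
      erFox <- vapply(modLab, function(nm)
        any(c("ERa", "FOXA1") %in% mods[[nm]]$factors), logical(1))
      diffFlag <- rep(FALSE, nSites)
      idx <- which(erFox)
      nDiff <- round(config$fracDifferentialSites * length(idx))
      if (nDiff > 0L) diffFlag[sample(idx, nDiff)] <- TRUE
      dir <- integer(nSites)
      dir[diffFlag] <- sample(c(-1L, 1L), sum(diffFlag), replace = TRUE)
      mcols(master)$differential <- diffFlag
      mcols(master)$diffDirection <- dir
    } else {
      master <- masterSites
      nSites <- length(master)
      centers <- mcols(master)$center
      modLab <- mcols(master)$module
    }

    patients <- .patientIds(config$nPatients)
    sampleTable <- do.call(rbind, lapply(config$factors, function(f) {
      nf <- config$nSamplesPerFactor[[f]]
      data.frame(sample_id = paste0(patients[seq_len(nf)], "_", f),
                 patient = patients[seq_len(nf)], factor = f)
    }))
    presence <- matrix(FALSE, nSites, nrow(sampleTable),
                       dimnames = list(mcols(master)$site_id,
                                       sampleTable$sample_id))
    dFlag <- mcols(master)$differential
    for (j in seq_len(nrow(sampleTable))) {
      f <- sampleTable$factor[j]
      rate <- vapply(modLab, function(nm)
        if (f %in% mods[[nm]]$factors) mods[[nm]]$presenceRate else 0,
        numeric(1))
      # LN-differential sites are robust consensus sites: constitutively
      # occupied in the factors that carry the group difference
      if (f %in% c("ERa", "FOXA1")) rate[dFlag & rate > 0] <- 1
      presence[, j] <- stats::runif(nSites) < rate
    }
    peakSets <- lapply(seq_len(nrow(sampleTable)), function(j) {
      on <- which(presence[, j])
      if (length(on) == 0L)
        return(PeakSet(GRanges(), sampleTable$sample_id[j],
                       sampleTable$factor[j]))
      cen <- centers[on] + round(stats::runif(length(on),
                                              -config$peakJitter,
                                              config$peakJitter))
      w <- round(stats::runif(length(on), config$peakWidthRange[1L],
                              config$peakWidthRange[2L]))
      st <- pmax(1L, as.integer(cen - w %/% 2L))
      en <- pmin(as.integer(gl), as.integer(cen + w %/% 2L))
      gr <- GRanges(config$chrom, IRanges(st, en))
      seqlengths(gr) <- stats::setNames(as.integer(gl), config$chrom)
      PeakSet(gr, sampleTable$sample_id[j], sampleTable$factor[j])
    })
    names(peakSets) <- sampleTable$sample_id
    list(masterSites = master, peakSets = peakSets, presence = presence,
         sampleTable = sampleTable)
  })
}

#' Generate negative-binomial read counts over the master sites
#'
#' count ~ NegBin(mean = depth_sample x (bound ? boundMean : background) x
#' patientEffect, size = countDispersion); at differential sites the bound
#' mean of lymph-node positive patients is multiplied by
#' differentialFold^direction. The patient-by-site effect is shared across
#' factors, planting within-patient correlation between co-binding factors.
#'
#' @param landscape output of \code{\link{generatePeakLandscape}}.
#' @param config a \code{\link{cohortConfig}}.
#' @param lnStatus named character ("neg"/"pos") per patient.
#' @param depths optional per-sample sequencing depth multipliers (default:
#'   drawn log-normal); a zero depth yields an all-zero column.
#' @param seed RNG seed.
#' @return \code{SummarizedExperiment} (sites x samples) with assay
#'   \code{counts} and colData (patient, factor, ln_status, depth).
#' @export
generateCounts <- function(landscape, config, lnStatus, depths = NULL,
                           seed = config$seed + 1L) {
  .withSeed(seed, {
    master <- landscape$masterSites
    st <- landscape$sampleTable
    nSites <- length(master); nSamp <- nrow(st)
    patients <- .patientIds(config$nPatients)
    pEff <- matrix(exp(stats::rnorm(config$nPatients * nSites, 0,
                                    config$patientEffectSd)),
                   nSites, config$nPatients,
                   dimnames = list(NULL, patients))
    depth <- if (is.null(depths)) exp(stats::rnorm(nSamp, 0, 0.3)) else
      rep_len(depths, nSamp)
    counts <- matrix(0L, nSites, nSamp,
                     dimnames = list(mcols(master)$site_id, st$sample_id))
    dFlag <- mcols(master)$differential
    dDir <- mcols(master)$diffDirection
    for (j in seq_len(nSamp)) {
      pat <- st$patient[j]
      bound <- landscape$presence[, j]
      mu <- ifelse(bound, config$boundMean * pEff[, pat],
                   config$backgroundMean)
      if (st$factor[j] %in% c("ERa", "FOXA1") && lnStatus[[pat]] == "pos")
        mu <- mu * ifelse(dFlag & bound, config$differentialFold^dDir, 1)
      counts[, j] <- stats::rnbinom(nSites, mu = depth[j] * mu,
                                    size = config$countDispersion)
    }
    storage.mode(counts) <- "integer"
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowRanges = master)
    colData(se) <- S4Vectors::DataFrame(
      patient = st$patient, factor = st$factor,
      ln_status = unname(unlist(lnStatus[st$patient])), depth = depth,
      row.names = st$sample_id)
    se
  })
}

# Cohort-pair-shareable expression trait: which genes carry the prognostic
# signal, their effect signs and baseline means.
.exprTrait <- function(annotation, masterSites, config, seed) {
  .withSeed(seed, {
    diffSites <- masterSites[mcols(masterSites)$differential]
    targets <- assignTargetGenes(diffSites, annotation, 20000L)
    if (nrow(targets) == 0L && config$nSignatureGenes > 0L)
      stop("no gene is proximal (<20 kb) to any differential site; ",
           "increase nGenes, gene density or fracDifferentialSites")
    pool <- sort(unique(targets$gene_id))
    nSig <- min(config$nSignatureGenes, length(pool))
    sigGenes <- sort(sample(pool, nSig))
    list(baseMeans = stats::setNames(
           exp(stats::rnorm(config$nGenes, config$baselineExprMeanLog,
                            config$baselineExprSdLog)),
           mcols(annotation)$gene_id),
         sigGenes = sigGenes,
         signs = stats::setNames(sample(c(-1, 1), nSig, replace = TRUE),
                                 sigGenes),
         targetTable = targets)
  })
}

#' Generate expression, clinical table and ground truth
#'
#' Signature genes are drawn from genes proximal (<20 kb or in the gene
#' body) to differential sites; their expression is shifted
#' \code{expressionFold}-fold between lymph-node groups (sign per gene).
#' The true risk score is the standardized signed mean of signature-gene
#' log2 expression; overall and distant-metastasis-free survival times are
#' exponential with hazard \code{baselineHazard * exp(gamma * risk)},
#' censored by independent exponential censoring times calibrated to the
#' configured censoring fraction.
#'
#' @param annotation gene \code{GRanges}.
#' @param masterSites master site \code{GRanges} carrying
#'   \code{differential} flags.
#' @param config a \code{\link{cohortConfig}}.
#' @param lnStatus optional named "neg"/"pos" per patient (drawn from
#'   \code{lnPositiveRate} if NULL).
#' @param trait optional shared expression trait (internal; lets a
#'   validation cohort reuse the discovery cohort's signature genes).
#' @param seed RNG seed.
#' @return list: \code{expression} (\code{SummarizedExperiment} genes x
#'   patients), \code{clinical} (data.frame), \code{groundTruth} (list).
#' @export
generateExpressionAndClinical <- function(annotation, masterSites, config,
                                          lnStatus = NULL, trait = NULL,
                                          seed = config$seed + 2L) {
  if (is.null(trait))
    trait <- .exprTrait(annotation, masterSites, config, seed = seed * 2L + 1L)
  .withSeed(seed, {
    patients <- .patientIds(config$nPatients)
    if (is.null(lnStatus))
      lnStatus <- stats::setNames(
        ifelse(stats::runif(config$nPatients) < config$lnPositiveRate,
               "pos", "neg"), patients)
    genes <- mcols(annotation)$gene_id
    nG <- length(genes); nP <- length(patients)
    depth <- exp(stats::rnorm(nP, 0, 0.2))
    lfold <- log(config$expressionFold)
    shift <- matrix(0, nG, nP, dimnames = list(genes, patients))
    pos <- lnStatus[patients] == "pos"
    shift[trait$sigGenes, pos] <- trait$signs[trait$sigGenes] %o%
      rep(lfold, sum(pos))
    mu <- (trait$baseMeans[genes] %o% depth) * exp(shift)
    counts <- matrix(stats::rnbinom(nG * nP, mu = mu,
                                    size = config$expressionDispersion),
                     nG, nP, dimnames = list(genes, patients))
    logex <- log2(t(t(counts) / depth) + 1)
    zsig <- scale(t(logex[trait$sigGenes, , drop = FALSE]))
    zsig[!is.finite(zsig)] <- 0
    raw <- drop(zsig %*% trait$signs[trait$sigGenes])
    risk <- if (stats::sd(raw) > 0) (raw - mean(raw)) / stats::sd(raw)
            else raw
    h <- config$baselineHazard * exp(config$hazardCoefficient * risk)
    drawEndpoint <- function(hEnd) {
      tEv <- stats::rexp(nP, hEnd)
      if (config$censoringRate == 0) {
        list(time = tEv, event = rep(1L, nP))
      } else {
        rateC <- config$baselineHazard *
          config$censoringRate / (1 - config$censoringRate)
        tC <- stats::rexp(nP, rateC)
        list(time = pmin(tEv, tC), event = as.integer(tEv <= tC))
      }
    }
    os <- drawEndpoint(h)
    dmfs <- drawEndpoint(1.5 * h)
    subtype <- ifelse(stats::runif(nP) < 0.85,
                      ifelse(risk > stats::median(risk), "M1", "M2"),
                      ifelse(risk > stats::median(risk), "M2", "M1"))
    clinical <- data.frame(
      sample_id = patients, ln_status = unname(lnStatus[patients]),
      subtype = subtype, os_time = os$time, os_event = os$event,
      dmfs_time = dmfs$time, dmfs_event = dmfs$event,
      age = round(stats::rnorm(nP, 65, 8)),
      endocrine = stats::rbinom(nP, 1L, 0.6),
      chemo = stats::rbinom(nP, 1L, 0.4),
      radio = stats::rbinom(nP, 1L, 0.5))
    se <- SummarizedExperiment(assays = list(counts = counts))
    colData(se) <- S4Vectors::DataFrame(
      patient = patients, ln_status = unname(lnStatus[patients]),
      row.names = patients)
    list(expression = se, clinical = clinical,
         groundTruth = list(
           differentialSiteIds =
             mcols(masterSites)$site_id[mcols(masterSites)$differential],
           signatureGeneIds = trait$sigGenes,
           signatureSigns = trait$signs,
           lnStatus = lnStatus, subtype = stats::setNames(subtype, patients),
           trueRisk = stats::setNames(risk, patients)),
         trait = trait)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs annotation, peak landscape, clinical labels, site counts and
#' expression generation under a single root seed; identical config + seed
#' yields an identical cohort.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param trait optional shared expression trait (see
#'   \code{\link{simulateCohortPair}}).
#' @param seed root seed (default: the config's).
#' @param annotation,masterSites optional shared genome layout; drawn from
#'   the seed when NULL.
#' @return list: annotation, landscape (master sites, peak sets, presence,
#'   sample table), siteCounts (\code{SummarizedExperiment}), expression,
#'   clinical, groundTruth, config.
#' @export
simulateCohort <- function(config, trait = NULL, seed = config$seed,
                           annotation = NULL, masterSites = NULL) {
  if (is.null(annotation))
    annotation <- generateGeneAnnotation(config, seed = seed)
  landscape <- generatePeakLandscape(config, annotation, seed = seed + 10L,
                                     masterSites = masterSites)
  lnStatus <- .withSeed(seed + 20L, stats::setNames(
    ifelse(stats::runif(config$nPatients) < config$lnPositiveRate,
           "pos", "neg"), .patientIds(config$nPatients)))
  siteCounts <- generateCounts(landscape, config, lnStatus,
                               seed = seed + 30L)
  ec <- generateExpressionAndClinical(annotation, landscape$masterSites,
                                      config, lnStatus = lnStatus,
                                      trait = trait, seed = seed + 40L)
  list(annotation = annotation, landscape = landscape,
       siteCounts = siteCounts, expression = ec$expression,
       clinical = ec$clinical, groundTruth = ec$groundTruth,
       trait = ec$trait, config = config)
}

#' Simulate a discovery/validation cohort pair
#'
#' Both cohorts share the genome, gene annotation, master-site landscape
#' architecture and - crucially - the planted signature genes and effect
#' signs, but draw independent patients, presence, counts, expression and
#' survival, emulating a discovery cohort and an independent validation
#' cohort measured on the same biology.
#'
#' @param config a \code{\link{cohortConfig}} (discovery design).
#' @param nValidationPatients validation cohort size (default 66).
#' @param seed root seed.
#' @return list(discovery=, validation=) of \code{\link{simulateCohort}}
#'   outputs.
#' @export
simulateCohortPair <- function(config, nValidationPatients = 66L,
                               seed = config$seed) {
  annotation <- generateGeneAnnotation(config, seed = seed)
  landscape <- generatePeakLandscape(config, annotation, seed = seed + 10L)
  trait <- .exprTrait(annotation, landscape$masterSites, config,
                      seed = seed + 5L)
  disc <- simulateCohort(config, trait = trait, seed = seed,
                         annotation = annotation,
                         masterSites = landscape$masterSites)
  vcfg <- config
  vcfg$nPatients <- as.integer(nValidationPatients)
  vcfg <- do.call(cohortConfig, unclass(vcfg))
  valid <- simulateCohort(vcfg, trait = trait, seed = seed + 1000L,
                          annotation = annotation,
                          masterSites = landscape$masterSites)
  list(discovery = disc, validation = valid)
}

#' Write a simulated cohort to plain-text files
#'
#' Per-sample peak BEDs (\code{peaks/<sample>.bed}), master site BED, site
#' count TSV, expression TSV, clinical TSV and ground-truth JSON.
#'
#' @param cohort output of \code{\link{simulateCohort}}.
#' @param dir output directory (created).
#' @return character vector of written paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (ps in cohort$landscape$peakSets) {
    p <- file.path(dir, "peaks", paste0(sampleId(ps), ".bed"))
    writePeakBed(ps, p); paths <- c(paths, p)
  }
  p <- file.path(dir, "master_sites.bed")
  writePeakBed(cohort$landscape$masterSites, p); paths <- c(paths, p)
  p <- file.path(dir, "annotation.bed")
  writeGeneAnnotation(cohort$annotation, p); paths <- c(paths, p)
  p <- file.path(dir, "site_counts.tsv")
  writeMatrixTsv(assay(cohort$siteCounts, "counts"), p); paths <- c(paths, p)
  p <- file.path(dir, "expression_counts.tsv")
  writeMatrixTsv(assay(cohort$expression, "counts"), p); paths <- c(paths, p)
  p <- file.path(dir, "clinical.tsv")
  utils::write.table(cohort$clinical, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(cohort$groundTruth, p, auto_unbox = TRUE,
                       digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
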