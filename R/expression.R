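#' @include binding-matrix.R
#' @importFrom DESeq2 estimateSizeFactorsForMatrix
NULL

#' Filter expression samples by read support
#'
#' Two readings of "at least \code{minReads} reads across each gene" are
#' available. \code{rule = "per-gene"} (default, the literal reading):
#' a sample is retained iff every gene of \code{geneSubset} has at least
#' \code{minReads} counts in it. \code{rule = "total"}: a sample is retained
#' iff its total count is at least \code{minReads * nGenes}. The removed
#' sample ids are attached as attribute \code{"removed"}.
#'
#' @param x gene-by-sample count matrix or \code{SummarizedExperiment}.
#' @param minReads minimum reads (default 5).
#' @param rule "per-gene" or "total".
#' @param geneSubset genes the per-gene rule is evaluated over (default all).
#' @return filtered object of the same type.
#' @export
filterSamples <- function(x, minReads = 5L, rule = c("per-gene", "total"),
                          geneSubset = NULL) {
  rule <- match.arg(rule)
  m <- .asCounts(x)
  sub <- if (is.null(geneSubset)) m else {
    missing <- setdiff(geneSubset, rownames(m))
    if (length(missing)) stop("geneSubset genes absent: ",
                              paste(missing, collapse = ", "))
    m[geneSubset, , drop = FALSE]
  }
  keep <- if (rule == "per-gene") {
    apply(sub, 2L, min) >= minReads
  } else {
    colSums(sub) >= minReads * nrow(sub)
  }
  if (!any(keep)) stop("filter removed every sample")
  out <- if (is(x, "SummarizedExperiment")) x[, keep] else
    m[, keep, drop = FALSE]
  attr(out, "removed") <- colnames(m)[!keep]
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes of count / per-gene geometric
#' mean, taken over genes whose geometric mean is nonzero (i.e. genes with
#' no zero count). Delegates to
#' \code{DESeq2::estimateSizeFactorsForMatrix}.
#'
#' @param x gene-by-sample count matrix or \code{SummarizedExperiment}.
#' @return named numeric vector of per-sample factors.
#' @export
sizeFactors <- function(x) {
  m <- .asCounts(x)
  if (!any(rowSums(m > 0) == ncol(m)))
    stop("no gene has nonzero counts in every sample; size factors undefined")
  estimateSizeFactorsForMatrix(m)
}

#' Size-factor-normalized log2 expression
#'
#' log2(count / factor + 1), a fully specified variance-dampening stand-in
#' for regularized-log transforms whose shrinkage is package-internal.
#'
#' @param x gene-by-sample count matrix or \code{SummarizedExperiment}.
#' @param factors per-sample size factors (default
#'   \code{\link{sizeFactors}(x)}); must be positive.
#' @return same type as input; a \code{SummarizedExperiment} gains a
#'   \code{normalized} assay.
#' @export
normalizeLog <- function(x, factors = sizeFactors(x)) {
  m <- .asCounts(x)
  if (any(factors <= 0)) stop("size factors must be positive")
  if (length(factors) != ncol(m)) stop("one factor per sample required")
  norm <- log2(sweep(m, 2L, factors, `/`) + 1)
  if (is(x, "SummarizedExperiment")) {
    assay(x, "normalized") <- norm
    x
  } else norm
}

#' Two-group expression subtype assignment from a classifier gene list
#'
#' Row-standardizes (z-score) the normalized expression of the classifier
#' genes, clusters samples agglomeratively (Ward linkage on Euclidean
#' distance of the z-scored profiles), cuts into two groups, and labels
#' them: the group with the higher mean z-score over \code{markerGenes}
#' (default: all classifier genes) is called \code{"M1"}, the other
#' \code{"M2"}. Invariant to gene and sample order.
#'
#' @param x \code{SummarizedExperiment} with a \code{normalized} assay or a
#'   normalized gene-by-sample matrix.
#' @param classifierGenes character vector of gene ids (>= 2 present).
#' @param markerGenes genes anchoring the "M1" label (subset of
#'   classifierGenes).
#' @return named character vector of labels in c("M1", "M2").
#' @export
subtypeCluster <- function(x, classifierGenes, markerGenes = classifierGenes) {
  m <- if (is(x, "SummarizedExperiment")) {
    if (!"normalized" %in% assayNames(x))
      stop("run normalizeLog() first: no 'normalized' assay")
    assay(x, "normalized")
  } else as.matrix(x)
  genes <- intersect(classifierGenes, rownames(m))
  if (length(genes) < 2L) stop("need at least 2 classifier genes in matrix")
  sub <- m[sort(genes), sort(colnames(m)), drop = FALSE]
  z <- t(scale(t(sub)))
  z[!is.finite(z)] <- 0  # constant genes carry no information
  hc <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  grp <- stats::cutree(hc, k = 2L)
  marker <- intersect(markerGenes, rownames(z))
  if (length(marker) == 0L) marker <- rownames(z)
  means <- tapply(colMeans(z[marker, , drop = FALSE])[names(grp)], grp, mean)
  m1 <- as.integer(names(which.max(means)))
  labels <- ifelse(grp == m1, "M1", "M2")
  labels[colnames(m)]
}
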