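#' @include genomic-intervals.R
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- assayNames colData colData<- rowRanges
NULL

#' Count fragments in disjoint binding sites
#'
#' A fragment is counted in the unique site containing its midpoint (so each
#' fragment contributes at most once). Sites must be non-overlapping, as in
#' a merged consensus union.
#'
#' @param fragments \code{GRanges} or \linkS4class{PeakSet} of one sample's
#'   sequenced fragments.
#' @param sites disjoint \code{GRanges} or \linkS4class{ConsensusSiteSet}.
#' @return integer vector of counts, one per site.
#' @export
countInSites <- function(fragments, sites) {
  fr <- if (is(fragments, "PeakSet")) peakRanges(fragments) else fragments
  gr <- if (is(sites, "ConsensusSiteSet")) peakRanges(sites) else sites
  if (length(gr) > 1L &&
      length(reduce(gr, ignore.strand = TRUE)) != length(gr))
    stop("sites overlap; fragment assignment would be ambiguous")
  if (length(fr) == 0L) return(integer(length(gr)))
  mid <- GRanges(seqnames(fr),
                 IRanges(start(fr) + (width(fr) - 1L) %/% 2L, width = 1L))
  as.integer(countOverlaps(gr, mid, ignore.strand = TRUE))
}

#' Build a site-by-sample count matrix
#'
#' @param fragmentSets named list of per-sample fragment \code{GRanges} (or
#'   \linkS4class{PeakSet}s); names become sample ids.
#' @param sites disjoint sites (\code{GRanges} or
#'   \linkS4class{ConsensusSiteSet}).
#' @param colData optional \code{DataFrame}/data.frame of per-sample
#'   metadata (factor, patient, group).
#' @return \code{SummarizedExperiment} with assay \code{counts}, rowRanges =
#'   sites and row names = \code{siteIds(sites)}.
#' @export
buildCountMatrix <- function(fragmentSets, sites, colData = NULL) {
  gr <- if (is(sites, "ConsensusSiteSet")) peakRanges(sites) else sites
  counts <- vapply(fragmentSets, countInSites, integer(length(gr)),
                   sites = gr)
  if (length(gr) == 1L) counts <- matrix(counts, nrow = 1L,
                                         dimnames = list(NULL, names(fragmentSets)))
  rownames(counts) <- siteIds(gr)
  se <- SummarizedExperiment(assays = list(counts = counts), rowRanges = gr)
  if (!is.null(colData)) colData(se) <- S4Vectors::DataFrame(colData)
  se
}

.asCounts <- function(x, assayName = "counts") {
  if (is(x, "SummarizedExperiment")) assay(x, assayName) else as.matrix(x)
}

#' Depth-normalize and log-transform a count matrix
#'
#' Scales each column to the median column total and applies log2(x + 1).
#' Columns whose total is zero are left as zeros with a warning.
#'
#' @param x count matrix or \code{SummarizedExperiment} with a \code{counts}
#'   assay.
#' @return same type as the input; for a \code{SummarizedExperiment} the
#'   result gains a \code{normalized} assay, for a matrix the normalized
#'   matrix is returned.
#' @export
normalizeCounts <- function(x) {
  m <- .asCounts(x)
  tot <- colSums(m)
  if (all(tot == 0)) stop("all columns have zero total")
  if (any(tot == 0))
    warning("all-zero column(s) left as zeros: ",
            paste(colnames(m)[tot == 0], collapse = ", "))
  target <- stats::median(tot[tot > 0])
  scl <- ifelse(tot > 0, target / tot, 0)
  norm <- log2(sweep(m, 2L, scl, `*`) + 1)
  if (is(x, "SummarizedExperiment")) {
    assay(x, "normalized") <- norm
    x
  } else norm
}

#' Sample-sample Pearson correlation matrix
#'
#' Pairwise Pearson correlation between sample columns of the normalized
#' layer (heavy-tailed raw counts would otherwise dominate r).
#'
#' @param x \code{SummarizedExperiment} with a \code{normalized} assay (see
#'   \code{\link{normalizeCounts}}) or a normalized numeric matrix.
#' @return symmetric correlation matrix with unit diagonal, sample ids as
#'   dimnames.
#' @export
correlationMatrix <- function(x) {
  m <- if (is(x, "SummarizedExperiment")) {
    if (!"normalized" %in% assayNames(x))
      stop("run normalizeCounts() first: no 'normalized' assay")
    assay(x, "normalized")
  } else as.matrix(x)
  if (ncol(m) < 2L || nrow(m) < 2L)
    stop("need at least 2 samples and 2 sites")
  v <- apply(m, 2L, stats::var)
  if (any(v == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(m)[v == 0], collapse = ", "))
  r <- stats::cor(m)
  diag(r) <- 1
  r
}

#' Agglomerative clustering of a correlation matrix
#'
#' Average-linkage hierarchical clustering on distance 1 - r. Samples are
#' ordered lexicographically by id before linkage so the dendrogram (and any
#' tie-breaking inside hclust) is deterministic for a given matrix.
#'
#' @param corr symmetric correlation matrix with dimnames.
#' @param nGroups number of groups to cut the tree into.
#' @return list with \code{labels} (named integer group per sample),
#'   \code{order} (leaf order) and the \code{hclust} object.
#' @export
hierarchicalCluster <- function(corr, nGroups) {
  if (nGroups > ncol(corr)) stop("nGroups exceeds the number of samples")
  ord <- order(colnames(corr))
  corr <- corr[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(1 - corr), method = "average")
  labels <- stats::cutree(hc, k = nGroups)
  list(labels = labels, order = hc$labels[hc$order], hclust = hc)
}
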