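#' @include accessors.R
NULL

#' Consensus support threshold for a factor profiled in n samples
#'
#' Reproduces the per-factor thresholds used to call a binding site
#' "consensus": for two samples a site must be found in both; for three or
#' more, in at least \code{floor(n/2)} (never fewer than one). The published
#' per-factor pairs are 30->15, 10->5, 7->3, 4->2, 3->1 and 2->2; note the
#' odd-n values are floor(n/2), not ceiling, so the rule is exposed here as
#' its own function and can be overridden wherever it is consumed.
#'
#' @param n number of samples profiled for the factor (>= 1).
#' @return integer threshold k.
#' @examples
#' consensusThreshold(30) # 15
#' consensusThreshold(7)  # 3
#' consensusThreshold(2)  # 2
#' @export
consensusThreshold <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("n must be a single integer >= 1")
  if (n == 2L) return(2L)
  max(1L, n %/% 2L)
}

#' Dual peak-caller intersection
#'
#' Keeps only the caller-A peaks corroborated by caller B: an A peak is
#' retained iff it overlaps at least one B peak by >= 1 bp. A is the
#' reference; B's coordinates are discarded.
#'
#' @param peaksA,peaksB \linkS4class{PeakSet}s from the two callers for the
#'   same sample and factor.
#' @return A \linkS4class{PeakSet} (subset of \code{peaksA}).
#' @export
intersectCallers <- function(peaksA, peaksB) {
  stopifnot(is(peaksA, "PeakSet"), is(peaksB, "PeakSet"))
  if (peaksA@sampleId != peaksB@sampleId ||
      peaksA@factorName != peaksB@factorName)
    stop("caller peak sets must describe the same sample and factor")
  keep <- countOverlaps(peaksA@ranges, peaksB@ranges,
                        ignore.strand = TRUE) > 0L
  PeakSet(peaksA@ranges[keep], peaksA@sampleId, peaksA@factorName)
}

#' Consensus binding sites across samples of one factor
#'
#' Single-linkage merges all samples' peaks into candidate regions, counts
#' how many distinct samples contribute at least one overlapping peak to each
#' region, and retains regions supported by at least \code{thresholdK}
#' samples.
#'
#' @param peaksets list of \linkS4class{PeakSet}, all the same factor.
#' @param thresholdK minimum number of supporting samples (defaults to
#'   \code{consensusThreshold(length(peaksets))}).
#' @return A \linkS4class{ConsensusSiteSet}.
#' @export
consensusSites <- function(peaksets,
                           thresholdK = consensusThreshold(length(peaksets))) {
  if (length(peaksets) == 0L) stop("need at least one PeakSet")
  stopifnot(all(vapply(peaksets, is, logical(1), "PeakSet")))
  fac <- unique(vapply(peaksets, factorName, character(1)))
  if (length(fac) != 1L)
    stop("all peak sets must describe the same factor")
  thresholdK <- as.integer(thresholdK)
  if (thresholdK > length(peaksets))
    stop("thresholdK cannot exceed the number of samples")
  pooled <- unlist(as(lapply(peaksets, peakRanges), "GRangesList"))
  cand <- reduce(pooled, ignore.strand = TRUE)
  support <- Reduce(`+`, lapply(peaksets, function(ps)
    as.integer(countOverlaps(cand, peakRanges(ps), ignore.strand = TRUE) > 0L)),
    integer(length(cand)))
  keep <- support >= thresholdK
  gr <- cand[keep]
  mcols(gr)$support <- support[keep]
  ConsensusSiteSet(gr, fac, length(peaksets), thresholdK)
}

#' Union of consensus site sets across factors
#'
#' Merged, non-overlapping union of all intervals; the region support is the
#' number of input sets contributing to each merged region.
#'
#' @param consensusSets list of \linkS4class{ConsensusSiteSet}.
#' @param factorName label for the union set (default "union").
#' @return A \linkS4class{ConsensusSiteSet} with thresholdK = 1.
#' @export
unionSites <- function(consensusSets, factorName = "union") {
  if (length(consensusSets) == 0L) stop("need at least one site set")
  grl <- lapply(consensusSets, peakRanges)
  merged <- reduce(unlist(as(grl, "GRangesList")), ignore.strand = TRUE)
  support <- Reduce(`+`, lapply(grl, function(g)
    as.integer(countOverlaps(merged, g, ignore.strand = TRUE) > 0L)),
    integer(length(merged)))
  mcols(merged)$support <- support
  ConsensusSiteSet(merged, factorName, length(consensusSets), 1L)
}

#' A-anchored overlap partition of two site sets
#'
#' Splits the intervals of A into those overlapping no B interval
#' (\code{aOnly}) and those overlapping at least one (\code{shared});
#' \code{bOnly} are the B intervals overlapping no A interval. Counting is
#' anchored on each set's own intervals, so
#' \code{length(aOnly) + length(shared) == length(A)}.
#'
#' @param setA,setB \linkS4class{ConsensusSiteSet}s (or GRanges).
#' @return list(aOnly=, shared=, bOnly=) of \code{GRanges}.
#' @export
overlapPartition <- function(setA, setB) {
  a <- if (is(setA, "ConsensusSiteSet")) peakRanges(setA) else setA
  b <- if (is(setB, "ConsensusSiteSet")) peakRanges(setB) else setB
  hitA <- countOverlaps(a, b, ignore.strand = TRUE) > 0L
  hitB <- countOverlaps(b, a, ignore.strand = TRUE) > 0L
  list(aOnly = a[!hitA], shared = a[hitA], bOnly = b[!hitB])
}

#' A-anchored overlap ratio
#'
#' Fraction of A's intervals overlapping at least one B interval. Asymmetric
#' by design (rows of an overlap-ratio heatmap are the anchor sets); a
#' symmetric Jaccard variant is available via \code{method = "jaccard"} and
#' a min-anchored one via \code{method = "min"}.
#'
#' @param setA,setB \linkS4class{ConsensusSiteSet}s (or GRanges).
#' @param method "anchor" (default), "jaccard" or "min".
#' @return numeric in [0, 1].
#' @export
overlapRatio <- function(setA, setB, method = c("anchor", "jaccard", "min")) {
  method <- match.arg(method)
  a <- if (is(setA, "ConsensusSiteSet")) peakRanges(setA) else setA
  b <- if (is(setB, "ConsensusSiteSet")) peakRanges(setB) else setB
  if (length(a) == 0L) stop("set A is empty; overlap ratio undefined")
  nA <- sum(countOverlaps(a, b, ignore.strand = TRUE) > 0L)
  switch(method,
    anchor = nA / length(a),
    jaccard = {
      nB <- sum(countOverlaps(b, a, ignore.strand = TRUE) > 0L)
      if (length(a) + length(b) - nA == 0) 0 else
        nA / (length(a) + length(b) - nA)
    },
    min = {
      if (length(b) == 0L) stop("set B is empty; min-anchored ratio undefined")
      nB <- sum(countOverlaps(b, a, ignore.strand = TRUE) > 0L)
      max(nA / length(a), nB / length(b))
    })
}

promoterWindows <- function(annotation, promoterWindow = 3000L) {
  tss <- ifelse(as.character(strand(annotation)) == "-",
                end(annotation), start(annotation))
  GRanges(seqnames(annotation),
          IRanges(pmax(1L, tss - as.integer(promoterWindow)),
                  tss + as.integer(promoterWindow)))
}

#' Genomic category distribution of binding sites
#'
#' Assigns each site exactly one category by midpoint with precedence
#' promoter > exon > intron > distal intergenic. The promoter is TSS +/- the
#' promoter window; a midpoint inside a gene body but outside promoter and
#' exons is intronic; everything else is distal intergenic. If the
#' annotation carries no exon models the exon fraction is zero and gene-body
#' midpoints count as intronic.
#'
#' @param sites \linkS4class{ConsensusSiteSet} or \code{GRanges}.
#' @param annotation gene \code{GRanges} (strand-aware, with
#'   \code{mcols()$gene_id}); exon models may be attached as
#'   \code{metadata(annotation)$exons} (a \code{GRanges}).
#' @param promoterWindow half-width of the promoter window in bp.
#' @return named numeric fractions over
#'   c("promoter","exon","intron","distal"); sums to 1 (empty input: all NA).
#' @export
genomicDistribution <- function(sites, annotation, promoterWindow = 3000L) {
  gr <- if (is(sites, "ConsensusSiteSet")) peakRanges(sites) else sites
  if (length(annotation) == 0L) stop("annotation must be non-empty")
  cats <- c("promoter", "exon", "intron", "distal")
  if (length(gr) == 0L)
    return(stats::setNames(rep(NA_real_, 4L), cats))
  mid <- GRanges(seqnames(gr),
                 IRanges(start(gr) + (width(gr) - 1L) %/% 2L, width = 1L))
  prom <- promoterWindows(annotation, promoterWindow)
  inProm <- countOverlaps(mid, prom, ignore.strand = TRUE) > 0L
  exons <- S4Vectors::metadata(annotation)$exons
  inExon <- if (is.null(exons)) rep(FALSE, length(mid)) else
    countOverlaps(mid, exons, ignore.strand = TRUE) > 0L
  inGene <- countOverlaps(mid, annotation, ignore.strand = TRUE) > 0L
  cat <- ifelse(inProm, "promoter",
         ifelse(inExon, "exon",
         ifelse(inGene, "intron", "distal")))
  tab <- table(factor(cat, levels = cats))
  as.numeric(tab) / length(gr) -> frac
  stats::setNames(frac, cats)
}

#' Assign proximal target genes to binding sites
#'
#' A gene is a potential target of a site iff the site overlaps the gene
#' body or the edge-to-edge gap between site and gene body is strictly less
#' than \code{maxDistance} (default 20 kb). Many-to-many: a site may map to
#' several genes and a gene to several sites.
#'
#' @param sites \linkS4class{ConsensusSiteSet} or \code{GRanges}.
#' @param annotation gene \code{GRanges} with \code{mcols()$gene_id}.
#' @param maxDistance bp; strict upper bound on the gap.
#' @return data.frame(site_id, gene_id, distance) with one row per pair;
#'   distance 0 for overlaps.
#' @export
assignTargetGenes <- function(sites, annotation, maxDistance = 20000L) {
  gr <- if (is(sites, "ConsensusSiteSet")) peakRanges(sites) else sites
  if (length(gr) == 0L || length(annotation) == 0L)
    return(data.frame(site_id = character(), gene_id = character(),
                      distance = integer()))
  # findOverlaps maxgap: pairs whose gap <= maxgap; gap < maxDistance
  hits <- findOverlaps(gr, annotation, maxgap = as.integer(maxDistance) - 1L,
                       ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(data.frame(site_id = character(), gene_id = character(),
                      distance = integer()))
  d <- distance(gr[queryHits(hits)], annotation[subjectHits(hits)],
                ignore.strand = TRUE)
  data.frame(site_id = siteIds(gr)[queryHits(hits)],
             gene_id = mcols(annotation)$gene_id[subjectHits(hits)],
             distance = as.integer(d))
}

#' Fixed-width windows around site midpoints
#'
#' Windows of +/- \code{halfWidth} bp around each site midpoint, clipped at
#' chromosome bounds (position 1 on the left; \code{seqlengths} on the right
#' when known). Used to extract read-profile matrices around peak centers.
#'
#' @param sites \linkS4class{ConsensusSiteSet} or \code{GRanges}.
#' @param halfWidth half-width in bp (default 5000, i.e. +/- 5 kb).
#' @return \code{GRanges} of windows, one per site.
#' @export
windowMatrix <- function(sites, halfWidth = 5000L) {
  gr <- if (is(sites, "ConsensusSiteSet")) peakRanges(sites) else sites
  halfWidth <- as.integer(halfWidth)
  # midpoint and window in BED space so an unclipped window spans exactly
  # 2*halfWidth bp: BED [center - halfWidth, center + halfWidth)
  center <- (start(gr) - 1L + end(gr)) %/% 2L
  st <- pmax(1L, center - halfWidth + 1L)
  en <- center + halfWidth
  sl <- seqlengths(gr)[as.character(seqnames(gr))]
  en <- as.integer(ifelse(!is.na(sl), pmin(en, sl), en))
  out <- GRanges(seqnames(gr), IRanges(st, en))
  seqlengths(out) <- seqlengths(gr)
  out
}
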