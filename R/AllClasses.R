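#' @import methods
#' @importFrom GenomicRanges GRanges granges start end width seqnames strand
#'   findOverlaps countOverlaps reduce distance resize mcols "mcols<-"
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits DataFrame metadata "metadata<-"
#' @importFrom GenomeInfoDb seqlengths "seqlengths<-" seqlevels
NULL

#' PeakSet: one sample's binding peaks for one factor
#'
#' A thin container pairing a sorted \link[GenomicRanges]{GRanges} of peak
#' intervals with the identity of the tumor sample and the profiled
#' transcription factor. All interval coordinates are 1-based closed
#' (GRanges convention); BED I/O converts from/to 0-based half-open.
#'
#' @slot sampleId character(1), tumor sample identifier.
#' @slot factorName character(1), e.g. \code{"ERa"} or \code{"FOXA1"}.
#' @slot ranges \code{GRanges} of peaks, sorted by (chrom, start).
#' @exportClass PeakSet
setClass("PeakSet",
  slots = c(sampleId = "character", factorName = "character",
            ranges = "GRanges"))

setValidity("PeakSet", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be length 1")
  if (length(object@factorName) != 1L)
    msg <- c(msg, "factorName must be length 1")
  o <- order(as.integer(seqnames(object@ranges)), start(object@ranges))
  if (!identical(o, seq_along(object@ranges)))
    msg <- c(msg, "ranges must be sorted by (chrom, start)")
  if (length(msg)) msg else TRUE
})

#' ConsensusSiteSet: factor-level consensus binding sites
#'
#' Non-overlapping merged regions supported by at least \code{thresholdK} of
#' the \code{nSamples} profiled samples for one factor. Per-region sample
#' support is kept in \code{mcols(ranges)$support}.
#'
#' @slot factorName character(1).
#' @slot ranges \code{GRanges} with a \code{support} metadata column.
#' @slot nSamples integer(1), number of samples the consensus was built from.
#' @slot thresholdK integer(1), minimum supporting samples per region.
#' @exportClass ConsensusSiteSet
setClass("ConsensusSiteSet",
  slots = c(factorName = "character", ranges = "GRanges",
            nSamples = "integer", thresholdK = "integer"))

setValidity("ConsensusSiteSet", function(object) {
  msg <- character()
  gr <- object@ranges
  if (!"support" %in% names(mcols(gr)))
    msg <- c(msg, "ranges must carry a 'support' metadata column")
  else if (length(gr) && any(mcols(gr)$support < object@thresholdK))
    msg <- c(msg, "every support must be >= thresholdK")
  if (length(gr) > 1L) {
    red <- reduce(gr, ignore.strand = TRUE)
    if (length(red) != length(gr))
      msg <- c(msg, "consensus intervals must be non-overlapping")
  }
  if (object@thresholdK > object@nSamples)
    msg <- c(msg, "thresholdK cannot exceed nSamples")
  if (length(msg)) msg else TRUE
})

#' SignatureModel: a linear prognostic gene-expression signature
#'
#' Intercept plus per-gene coefficients from a penalized logistic fit;
#' the risk score of a sample is \code{intercept + sum(coef * expr)} on the
#' normalized expression scale the model was trained on.
#'
#' @slot geneIds character, all candidate genes offered to the fit.
#' @slot coefficients named numeric, one per candidate gene (zeros kept).
#' @slot intercept numeric(1).
#' @slot alpha numeric(1), elastic-net mixing parameter.
#' @slot lambda numeric(1), selected penalty strength.
#' @slot metadata list: n, seed, lambda path, CV settings.
#' @exportClass SignatureModel
setClass("SignatureModel",
  slots = c(geneIds = "character", coefficients = "numeric",
            intercept = "numeric", alpha = "numeric", lambda = "numeric",
            metadata = "list"))

setValidity("SignatureModel", function(object) {
  msg <- character()
  if (length(object@coefficients) != length(object@geneIds))
    msg <- c(msg, "one coefficient per gene required")
  if (!identical(names(object@coefficients), object@geneIds))
    msg <- c(msg, "coefficients must be named by geneIds")
  if (object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in [0, 1]")
  if (object@lambda < 0) msg <- c(msg, "lambda must be non-negative")
  if (length(msg)) msg else TRUE
})
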