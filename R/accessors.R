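#' @include AllClasses.R
NULL

#' Construct a PeakSet
#'
#' @param ranges \code{GRanges} of peak intervals (sorted internally).
#' @param sampleId,factorName sample and factor identifiers.
#' @return A \linkS4class{PeakSet}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 501), width = 200))
#' PeakSet(gr, "S1", "ERa")
#' @export
PeakSet <- function(ranges, sampleId, factorName) {
  new("PeakSet", sampleId = as.character(sampleId),
      factorName = as.character(factorName),
      ranges = sort(ranges, ignore.strand = TRUE))
}

#' Construct a ConsensusSiteSet
#'
#' @param ranges \code{GRanges} with a \code{support} metadata column.
#' @param factorName factor identifier.
#' @param nSamples,thresholdK sample count and support threshold.
#' @return A \linkS4class{ConsensusSiteSet}.
#' @export
ConsensusSiteSet <- function(ranges, factorName, nSamples, thresholdK) {
  new("ConsensusSiteSet", factorName = as.character(factorName),
      ranges = ranges, nSamples = as.integer(nSamples),
      thresholdK = as.integer(thresholdK))
}

#' Accessors for cistroSig classes
#'
#' \code{peakRanges} returns the underlying \code{GRanges}; \code{sampleId},
#' \code{factorName}, \code{siteSupport}, \code{thresholdK} and
#' \code{nSamples} return the corresponding scalar/vector fields;
#' \code{siteIds} returns stable BED-convention identifiers
#' \code{"chrom:start-end"} (0-based half-open).
#'
#' @param x a \linkS4class{PeakSet} or \linkS4class{ConsensusSiteSet}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))
#' @rdname accessors
#' @export
setMethod("peakRanges", "PeakSet", function(x) x@ranges)
#' @rdname accessors
#' @export
setMethod("peakRanges", "ConsensusSiteSet", function(x) x@ranges)

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setMethod("sampleId", "PeakSet", function(x) x@sampleId)

#' @rdname accessors
#' @export
setGeneric("factorName", function(x) standardGeneric("factorName"))
#' @rdname accessors
#' @export
setMethod("factorName", "PeakSet", function(x) x@factorName)
#' @rdname accessors
#' @export
setMethod("factorName", "ConsensusSiteSet", function(x) x@factorName)

#' @rdname accessors
#' @export
setGeneric("siteSupport", function(x) standardGeneric("siteSupport"))
#' @rdname accessors
#' @export
setMethod("siteSupport", "ConsensusSiteSet",
          function(x) mcols(x@ranges)$support)

#' @rdname accessors
#' @export
setGeneric("thresholdK", function(x) standardGeneric("thresholdK"))
#' @rdname accessors
#' @export
setMethod("thresholdK", "ConsensusSiteSet", function(x) x@thresholdK)

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setMethod("nSamples", "ConsensusSiteSet", function(x) x@nSamples)

#' @rdname accessors
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))
#' @rdname accessors
#' @export
setMethod("siteIds", "GRanges", function(x)
  paste0(as.character(seqnames(x)), ":", start(x) - 1L, "-", end(x)))
#' @rdname accessors
#' @export
setMethod("siteIds", "ConsensusSiteSet", function(x) siteIds(x@ranges))
#' @rdname accessors
#' @export
setMethod("siteIds", "PeakSet", function(x) siteIds(x@ranges))

setMethod("length", "PeakSet", function(x) length(x@ranges))
setMethod("length", "ConsensusSiteSet", function(x) length(x@ranges))

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet:", length(object@ranges), "peaks |", object@factorName,
      "in sample", object@sampleId, "\n")
})

setMethod("show", "ConsensusSiteSet", function(object) {
  cat("ConsensusSiteSet:", length(object@ranges), "sites for",
      object@factorName, sprintf("(support >= %d of %d samples)\n",
      object@thresholdK, object@nSamples))
})

setMethod("show", "SignatureModel", function(object) {
  nz <- sum(object@coefficients != 0)
  cat("SignatureModel:", nz, "contributing genes of",
      length(object@geneIds), "candidates | alpha =", object@alpha,
      "| lambda =", signif(object@lambda, 4), "\n")
})

#' Genes contributing to a signature
#'
#' The reported signature is exactly the genes with nonzero coefficient.
#'
#' @param model a \linkS4class{SignatureModel}.
#' @return named numeric of nonzero coefficients.
#' @export
contributingGenes <- function(model) {
  stopifnot(is(model, "SignatureModel"))
  model@coefficients[model@coefficients != 0]
}

#' @describeIn contributingGenes full coefficient vector (zeros included).
#' @export
setMethod("coef", "SignatureModel", function(object) object@coefficients)
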