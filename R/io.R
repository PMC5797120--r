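#' @include accessors.R
NULL

#' Read and write peak BED files
#'
#' BED convention: 0-based half-open, columns chrom, start, end and
#' optionally name, score, strand. Internally coordinates become 1-based
#' closed \code{GRanges}.
#'
#' @param path file path.
#' @param sampleId,factorName identifiers attached to the resulting
#'   \linkS4class{PeakSet}.
#' @return \code{readPeakBed}: a \linkS4class{PeakSet};
#'   \code{writePeakBed}: the path, invisibly.
#' @export
readPeakBed <- function(path, sampleId, factorName) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[seq_len(min(6L, ncol(df)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[seq_len(
      min(6L, ncol(df)))]
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  if (!is.null(df$score)) mcols(gr)$score <- df$score
  PeakSet(gr, sampleId, factorName)
}

#' @rdname readPeakBed
#' @param x a \linkS4class{PeakSet}, \linkS4class{ConsensusSiteSet} or
#'   \code{GRanges}.
#' @export
writePeakBed <- function(x, path) {
  gr <- if (is(x, "GRanges")) x else peakRanges(x)
  score <- if ("support" %in% names(mcols(gr))) mcols(gr)$support
           else if ("score" %in% names(mcols(gr))) mcols(gr)$score
           else rep(0L, length(gr))
  df <- data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
                   end = end(gr), name = siteIds(gr), score = score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation from 6-column BED
#'
#' Expects chrom, start (0-based), end, gene_id, score, strand. The TSS is
#' the start for + genes and the end for - genes.
#'
#' @param path file path.
#' @return gene \code{GRanges} with \code{gene_id} and \code{tss} columns.
#' @export
readGeneAnnotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "gene_id",
                                        "score", "strand"))
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end), strand = df$strand)
  mcols(gr)$gene_id <- df$gene_id
  mcols(gr)$tss <- ifelse(df$strand == "-", df$end, df$start + 1L)
  sort(gr, ignore.strand = TRUE)
}

#' @rdname readGeneAnnotation
#' @param annotation gene \code{GRanges} as produced by
#'   \code{\link{generateGeneAnnotation}}.
#' @export
writeGeneAnnotation <- function(annotation, path) {
  df <- data.frame(chrom = as.character(seqnames(annotation)),
                   start = start(annotation) - 1L, end = end(annotation),
                   gene_id = mcols(annotation)$gene_id, score = 0L,
                   strand = as.character(strand(annotation)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a numeric matrix as TSV (rows = features, cols = samples)
#'
#' @param path file path.
#' @return \code{readMatrixTsv}: numeric matrix with dimnames.
#' @export
readMatrixTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE)
  as.matrix(df)
}

#' @rdname readMatrixTsv
#' @param m matrix with row and column names.
#' @export
writeMatrixTsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
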