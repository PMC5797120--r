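#' @include binding-matrix.R
NULL

#' Benjamini-Hochberg step-up q-values
#'
#' Thin validated wrapper over \code{stats::p.adjust(method = "BH")}.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return q-values, same length and order.
#' @export
benjaminiHochberg <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

# Vectorized Welch t-test across the rows of a matrix.
.rowWelch <- function(m, g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(m[, g1, drop = FALSE])
  m2 <- rowMeans(m[, g2, drop = FALSE])
  v1 <- rowSums((m[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((m[, g2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0] <- 1  # identical constant rows carry no evidence
  list(mean1 = m1, mean2 = m2, t = t, df = df, p = p)
}

#' Differential binding between two sample groups
#'
#' Per-site Welch t-test on the log-normalized layer, Benjamini-Hochberg
#' correction, and a significance call in one of two modes: \code{"fdr"}
#' (q < threshold, default 0.1, used when comparing two different factors)
#' or \code{"pvalue"} (p < threshold, default 0.01, used when comparing
#' clinical groups such as lymph-node status). Sites with zero counts in
#' every sample are dropped before testing.
#'
#' @param x \code{SummarizedExperiment} with \code{counts} (a
#'   \code{normalized} assay is added if missing) or a raw count matrix.
#' @param groups binary labels, one per sample column (factor/character/
#'   logical); exactly two levels, each with >= 2 samples.
#' @param mode "fdr" or "pvalue".
#' @param threshold significance cutoff; defaults to 0.1 for fdr mode and
#'   0.01 for pvalue mode.
#' @return data.frame(site_id, mean1, mean2, lfc, p, q, significant), one
#'   row per tested site; \code{lfc} is mean1 - mean2 on the log2 layer and
#'   level 1 is the first factor level of \code{groups}.
#' @export
differentialSites <- function(x, groups, mode = c("fdr", "pvalue"),
                              threshold = NULL) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- if (mode == "fdr") 0.1 else 0.01
  raw <- .asCounts(x)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 samples")
  if (length(groups) != ncol(raw))
    stop("one group label per sample column required")
  keep <- rowSums(raw) > 0
  norm <- if (is(x, "SummarizedExperiment") &&
              "normalized" %in% assayNames(x)) assay(x, "normalized")
          else normalizeCounts(raw)
  norm <- norm[keep, , drop = FALSE]
  g1 <- which(groups == levels(groups)[1L])
  g2 <- which(groups == levels(groups)[2L])
  w <- .rowWelch(norm, g1, g2)
  q <- benjaminiHochberg(w$p)
  sig <- if (mode == "fdr") q < threshold else w$p < threshold
  data.frame(site_id = rownames(norm), mean1 = w$mean1, mean2 = w$mean2,
             lfc = w$mean1 - w$mean2, p = w$p, q = q, significant = sig,
             row.names = NULL)
}
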