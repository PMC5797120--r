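# Brute-force oracles on tiny linear genomes. All coordinates are 1-based
# closed (the GRanges convention used inside the package); intervals are
# data.frames with integer start/end columns.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

grFromDf <- function(df, chrom = "chr1", L = NULL) {
  gr <- GRanges(chrom, IRanges(df$start, df$end))
  if (!is.null(L)) seqlengths(gr) <- setNames(as.integer(L), chrom)
  gr
}

dfFromGr <- function(gr) {
  data.frame(start = start(gr), end = end(gr))
}

randIntervals <- function(n, L, maxWidth = 200L) {
  if (n == 0L) return(data.frame(start = integer(), end = integer()))
  w <- sample.int(maxWidth, n, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(max(1L, L - wi), 1L), integer(1))
  df <- data.frame(start = s, end = pmin(L, s + w - 1L))
  df[order(df$start, df$end), , drop = FALSE]
}

.overlaps1 <- function(s1, e1, s2, e2) pmax(s1, s2) <= pmin(e1, e2)

# Per-base support scan: candidate regions are maximal runs of any
# coverage; support = number of samples contributing >= 1 overlapping peak.
bfConsensus <- function(peakDfs, k, L) {
  cov <- matrix(FALSE, L, length(peakDfs))
  for (i in seq_along(peakDfs)) {
    df <- peakDfs[[i]]
    for (r in seq_len(nrow(df))) cov[df$start[r]:df$end[r], i] <- TRUE
  }
  any <- rowSums(cov) > 0
  r <- rle(any)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(start = integer(), end = integer(),
                    support = integer())
  for (j in which(r$values)) {
    sup <- sum(vapply(seq_along(peakDfs), function(i)
      any(cov[starts[j]:ends[j], i]), logical(1)))
    if (sup >= k)
      out <- rbind(out, data.frame(start = starts[j], end = ends[j],
                                   support = sup))
  }
  out
}

bfUnion <- function(dfs, L) {
  covered <- rep(FALSE, L)
  for (df in dfs)
    for (r in seq_len(nrow(df)))
      covered[df$start[r]:df$end[r]] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

bfPartition <- function(a, b) {
  hitA <- vapply(seq_len(nrow(a)), function(i)
    any(.overlaps1(a$start[i], a$end[i], b$start, b$end)), logical(1))
  hitB <- vapply(seq_len(nrow(b)), function(i)
    any(.overlaps1(b$start[i], b$end[i], a$start, a$end)), logical(1))
  if (nrow(a) == 0L) hitA <- logical(0)
  if (nrow(b) == 0L) hitB <- logical(0)
  list(aOnly = a[!hitA, , drop = FALSE], shared = a[hitA, , drop = FALSE],
       bOnly = b[!hitB, , drop = FALSE])
}

# Midpoint classification, precedence promoter > exon > intron > distal.
bfGenomicDist <- function(sites, genes, exons = NULL, pw = 3000L) {
  mid <- sites$start + (sites$end - sites$start) %/% 2L
  tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  cls <- vapply(mid, function(m) {
    if (any(m >= pmax(1L, tss - pw) & m <= tss + pw)) return("promoter")
    if (!is.null(exons) && nrow(exons) > 0L &&
        any(m >= exons$start & m <= exons$end)) return("exon")
    if (any(m >= genes$start & m <= genes$end)) return("intron")
    "distal"
  }, character(1))
  tab <- table(factor(cls, levels = c("promoter", "exon", "intron",
                                      "distal")))
  as.numeric(tab) / length(mid)
}

# All-pairs edge-to-edge gap scan; gap 0 for overlapping or adjacent
# intervals, assignment iff overlap or gap < maxDist.
bfTargets <- function(sites, genes, maxDist = 20000L) {
  out <- data.frame(site = integer(), gene_id = character(),
                    distance = integer())
  for (i in seq_len(nrow(sites))) for (j in seq_len(nrow(genes))) {
    if (.overlaps1(sites$start[i], sites$end[i],
                   genes$start[j], genes$end[j])) {
      d <- 0L
    } else {
      d <- max(sites$start[i], genes$start[j]) -
        min(sites$end[i], genes$end[j]) - 1L
    }
    if (d < maxDist)
      out <- rbind(out, data.frame(site = i, gene_id = genes$gene_id[j],
                                   distance = d))
  }
  out
}

# Exhaustive sort-all-distances k-NN with the package's tie rules.
bfKnn <- function(trainX, labels, testX, k, p = 2) {
  apply(testX, 1L, function(x) {
    d <- apply(trainX, 1L, function(tr) sum(abs(x - tr)^p)^(1 / p))
    kth <- sort(d)[k]
    nb <- which(d <= kth)
    votes <- table(labels[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(lb)
        sum(d[nb][labels[nb] == lb]), numeric(1))
      top <- sort(top[sums == min(sums)])[1L]
    }
    top
  })
}

# Hand product-limit estimator (no grouping).
bfKm <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = numeric(), survival = numeric())
  for (t in ut) {
    nRisk <- sum(time >= t)
    nEv <- sum(time == t & event == 1)
    s <- s * (1 - nEv / nRisk)
    out <- rbind(out, data.frame(time = t, survival = s))
  }
  out
}

# Efron-corrected Cox log partial likelihood for a single covariate,
# assuming no tied event times (reduces to Breslow).
bfCoxLogLik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    atRisk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[atRisk])))
  }
  ll
}

# Small expression cohort with planted two-class signal, Gaussian on the
# normalized (log) scale.
plantedExpression <- function(n, pNoise, planted, shift, prefix = "g") {
  p <- pNoise + length(planted)
  genes <- c(planted, paste0(prefix, "noise", seq_len(pNoise)))
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, genes))
  x[, planted] <- x[, planted] + outer(y, rep(shift, length(planted)))
  list(x = x, y = y, genes = genes)
}
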