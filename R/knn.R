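NULL

#' Minkowski distance
#'
#' \eqn{d(x, y) = (\sum_i |x_i - y_i|^p)^{1/p}} for order p >= 1.
#'
#' @param x,y numeric vectors of equal length.
#' @param p Minkowski order (2 = Euclidean).
#' @return numeric distance.
#' @examples
#' minkowskiDistance(c(0, 0), c(3, 4)) # 5
#' @export
minkowskiDistance <- function(x, y, p = 2) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (p < 1) stop("Minkowski order must be >= 1")
  sum(abs(x - y)^p)^(1 / p)
}

#' k-nearest-neighbor outcome transfer in binding-site count space
#'
#' Each test sample is labeled by the majority outcome of its k nearest
#' training samples under Minkowski distance on the shared feature sites
#' (normalize counts first; sequencing depth otherwise dominates). Distance
#' ties at the k-th position include all tied neighbors; vote ties are
#' broken by the smaller summed neighbor distance, then by the
#' lexicographically smaller label, so predictions are deterministic and
#' independent of training-sample order.
#'
#' @param trainX,testX samples-by-sites numeric matrices over the same
#'   feature sites in the same order (checked via column names when
#'   present).
#' @param trainLabels outcome label per training sample.
#' @param k neighbors (default 5, the published choice).
#' @param p Minkowski order (default 2).
#' @return character vector of predicted labels, one per test sample.
#' @export
knnPredict <- function(trainX, trainLabels, testX, k = 5L, p = 2) {
  trainX <- as.matrix(trainX); testX <- as.matrix(testX)
  if (ncol(trainX) != ncol(testX) ||
      (!is.null(colnames(trainX)) && !is.null(colnames(testX)) &&
       !identical(colnames(trainX), colnames(testX))))
    stop("train and test must share the same feature sites in order")
  if (k < 1L || k > nrow(trainX)) stop("k must be in 1..n_train")
  if (length(trainLabels) != nrow(trainX))
    stop("one label per training sample required")
  trainLabels <- as.character(trainLabels)
  apply(testX, 1L, function(x) {
    d <- apply(trainX, 1L, function(tr) minkowskiDistance(x, tr, p))
    kth <- sort(d, partial = k)[k]
    nb <- which(d <= kth)  # all neighbors tied at the k-th distance
    votes <- tapply(rep(1L, length(nb)), trainLabels[nb], sum)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(lb)
        sum(d[nb][trainLabels[nb] == lb]), numeric(1))
      top <- top[sums == min(sums)]
      top <- sort(top)[1L]
    }
    top
  })
}
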