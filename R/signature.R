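#' @include accessors.R
#' @importFrom glmnet glmnet cv.glmnet
NULL

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# glmnet warns on class counts below 8 in every path/fold fit; class
# presence is validated before fitting, so that chatter is muffled.
.quietGlmnet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

.binaryY <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  u <- sort(unique(y))
  if (!all(u %in% c(0, 1)) || length(u) < 2L)
    stop("y must be binary with both classes present")
  as.numeric(y)
}

#' Fit an elastic-net logistic signature with cross-validated penalty
#'
#' Minimizes the penalized binomial deviance
#' \deqn{-\frac1n\sum_i [y_i \log p_i + (1-y_i)\log(1-p_i)] +
#'   \lambda[(1-\alpha)/2\,\|\beta\|_2^2 + \alpha\|\beta\|_1]}
#' over a decreasing lambda path (100 log-spaced values from the
#' all-zero-coefficient lambda down to 1e-4 of it), selecting lambda by
#' minimal mean cross-validated deviance. Leave-one-out folds are the
#' default. Predictors are standardized internally; coefficients are
#' reported on the original scale.
#'
#' @param X samples-by-genes numeric matrix with dimnames.
#' @param y binary outcome (0/1, logical, or 2-level factor whose second
#'   level is the positive class).
#' @param alpha elastic-net mixing parameter in [0, 1] (default 0.5).
#' @param nfolds number of CV folds; \code{NULL} (default) means
#'   leave-one-out.
#' @param lambda optional explicit decreasing lambda path (>= 2 values).
#' @param nlambda,lambdaMinRatio path construction when \code{lambda} is
#'   NULL.
#' @param seed integer seed controlling fold assignment when
#'   \code{nfolds < n}; irrelevant (but recorded) for leave-one-out.
#' @return A \linkS4class{SignatureModel}.
#' @export
fitElasticNet <- function(X, y, alpha = 0.5, nfolds = NULL, lambda = NULL,
                          nlambda = 100L, lambdaMinRatio = 1e-4,
                          seed = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 10L) stop("need at least 10 samples")
  y <- .binaryY(y)
  if (length(y) != nrow(X)) stop("one outcome per sample row required")
  if (!is.null(lambda) && length(lambda) < 2L)
    stop("degenerate lambda grid: supply >= 2 values or NULL")
  n <- nrow(X)
  loo <- is.null(nfolds) || nfolds >= n
  foldid <- if (loo) seq_len(n) else
    .withSeed(seed, sample(rep_len(seq_len(nfolds), n)))
  path <- if (is.null(lambda)) {
    fit0 <- .quietGlmnet(
      glmnet(X, y, family = "binomial", alpha = alpha, nlambda = nlambda,
             lambda.min.ratio = lambdaMinRatio, standardize = TRUE))
    fit0$lambda
  } else sort(lambda, decreasing = TRUE)
  cv <- .quietGlmnet(
    cv.glmnet(X, y, family = "binomial", alpha = alpha, lambda = path,
              foldid = foldid, type.measure = "deviance",
              standardize = TRUE, grouped = FALSE))
  co <- as.numeric(stats::coef(cv, s = "lambda.min"))
  genes <- colnames(X)
  new("SignatureModel", geneIds = genes,
      coefficients = stats::setNames(co[-1L], genes),
      intercept = co[1L], alpha = alpha, lambda = cv$lambda.min,
      metadata = list(n = n, seed = seed, lambdaPath = cv$lambda,
                      cvm = cv$cvm, loocv = loo,
                      nfolds = if (loo) n else nfolds))
}

#' Score samples with a signature model
#'
#' Linear predictor \code{intercept + X beta} on the expression scale the
#' model was trained on. Every model gene must be present; missing genes
#' are an error, never imputed.
#'
#' @param model \linkS4class{SignatureModel}.
#' @param X samples-by-genes matrix containing at least the model's genes.
#' @return named numeric risk score per sample.
#' @export
scoreSamples <- function(model, X) {
  stopifnot(is(model, "SignatureModel"))
  X <- as.matrix(X)
  missing <- setdiff(model@geneIds, colnames(X))
  if (length(missing))
    stop("genes required by the model are missing: ",
         paste(missing, collapse = ", "))
  drop(model@intercept +
       X[, model@geneIds, drop = FALSE] %*% model@coefficients)
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) statistic with half credit for ties; the
#' curve sweeps thresholds over the unique scores (predict positive iff
#' score >= threshold).
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (positive = 1/TRUE/second factor level).
#' @return list(thresholds, sensitivity, specificity, auc).
#' @export
rocAuc <- function(scores, labels) {
  y <- .binaryY(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)  # average ranks give the half-tie credit
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & y == 0) / n0, numeric(1))
  list(thresholds = thr, sensitivity = sens, specificity = spec, auc = auc)
}

#' Median split of risk scores into high- and low-risk groups
#'
#' Scores strictly above the median are "high", the rest "low"; with an
#' even number of distinct scores the groups have equal size. All-equal
#' scores therefore yield an all-"low" cohort (documented edge case).
#'
#' @param scores numeric risk scores (length >= 2).
#' @return character vector in c("high", "low"), named like scores.
#' @export
medianRiskSplit <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 scores")
  stats::setNames(ifelse(scores > stats::median(scores), "high", "low"),
                  names(scores))
}

#' Size-matched random-gene-set bootstrap null for classifier AUC
#'
#' Repeats the identical train-and-validate pipeline B times on gene sets
#' drawn uniformly without replacement from \code{geneUniverse}, each of
#' the same size as the observed candidate set, and compares the observed
#' validation AUC against the null AUC distribution with the one-tailed,
#' add-one-smoothed p-value \code{(1 + #\{AUC_b >= AUC_obs\}) / (B + 1)}
#' (never exactly zero). A failing replicate is logged and resampled, never
#' silently dropped.
#'
#' @param trainX,trainY,validX,validY discovery and validation expression
#'   (samples x genes) and binary outcomes.
#' @param geneUniverse genes the random sets are drawn from (columns of
#'   both matrices).
#' @param setSize genes per random set.
#' @param B number of bootstrap models (paper default 1000).
#' @param seed integer seed for the whole resampling stream.
#' @param alpha,nfolds passed to \code{\link{fitElasticNet}}.
#' @param aucObserved observed AUC; if NULL it is computed from
#'   \code{observedGenes} with the identical pipeline.
#' @param observedGenes the observed candidate gene set.
#' @param ... further arguments to \code{\link{fitElasticNet}} (e.g.
#'   \code{nlambda}); applied identically to observed and null fits.
#' @return list(aucObserved, nullAuc (length B), p, B, failures).
#' @export
bootstrapNull <- function(trainX, trainY, validX, validY, geneUniverse,
                          setSize, B = 1000L, seed = 1L, alpha = 0.5,
                          nfolds = NULL, aucObserved = NULL,
                          observedGenes = NULL, ...) {
  stopifnot(B >= 1L, setSize >= 1L)
  geneUniverse <- intersect(geneUniverse, colnames(trainX))
  if (setSize > length(geneUniverse))
    stop("setSize exceeds the gene universe")
  onePipeline <- function(genes)
    rocAuc(scoreSamples(
      fitElasticNet(trainX[, genes, drop = FALSE], trainY, alpha = alpha,
                    nfolds = nfolds, seed = seed, ...),
      validX[, genes, drop = FALSE]), validY)$auc
  if (is.null(aucObserved)) {
    if (is.null(observedGenes))
      stop("supply either aucObserved or observedGenes")
    aucObserved <- onePipeline(observedGenes)
  }
  failures <- 0L
  nullAuc <- .withSeed(seed, {
    out <- numeric(B)
    b <- 1L
    while (b <= B) {
      genes <- sample(geneUniverse, setSize)
      val <- tryCatch(onePipeline(genes), error = function(e) {
        message("bootstrap replicate failed (resampled): ",
                conditionMessage(e))
        NA_real_
      })
      if (is.na(val)) {
        failures <- failures + 1L
        if (failures > 10L * B) stop("bootstrap pipeline keeps failing")
        next
      }
      out[b] <- val
      b <- b + 1L
    }
    out
  })
  list(aucObserved = aucObserved, nullAuc = nullAuc,
       p = (1 + sum(nullAuc >= aucObserved)) / (B + 1), B = B,
       failures = failures)
}

#' Train and validate one signature per candidate feature set
#'
#' Runs the identical elastic-net pipeline for each named gene set (e.g.
#' ERa targets, FOXA1 targets, and their union) and returns the validation
#' ROC/AUC of each, enabling the "union outperforms its parts" comparison.
#'
#' @inheritParams bootstrapNull
#' @param sets named list of non-empty gene-id vectors.
#' @return named list; per set: list(model, roc).
#' @export
compareFeatureSets <- function(trainX, trainY, validX, validY, sets,
                               alpha = 0.5, nfolds = NULL, seed = NULL) {
  if (length(sets) == 0L || any(lengths(sets) == 0L))
    stop("every feature set must be non-empty")
  lapply(sets, function(genes) {
    genes <- intersect(genes, colnames(trainX))
    if (length(genes) == 0L) stop("feature set has no genes in the matrix")
    model <- fitElasticNet(trainX[, genes, drop = FALSE], trainY,
                           alpha = alpha, nfolds = nfolds, seed = seed)
    roc <- rocAuc(scoreSamples(model, validX[, genes, drop = FALSE]),
                  validY)
    list(model = model, roc = roc)
  })
}
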