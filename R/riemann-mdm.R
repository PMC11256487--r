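# Single-epoch oddball/standard classification: ERP super-trial
# (prototype-augmented) covariances, the affine-invariant Riemannian
# geometry of SPD matrices (distance, Karcher mean), the
# minimum-distance-to-means classifier and its cross-validated evaluation.

.assertSpd <- function(A, what = "matrix", tol = 1e-8) {
  stopIf(!is.matrix(A) || nrow(A) != ncol(A), "%s must be square", what)
  stopIf(max(abs(A - t(A))) > tol * max(1, max(abs(A))),
         "%s is not symmetric", what)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  stopIf(min(ev) <= 0, "%s is not positive definite (min eigenvalue %g)",
         what, min(ev))
  invisible(ev)
}

.spdPow <- function(A, p) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  e$vectors %*% (e$values^p * t(e$vectors))
}

.spdLog <- function(A) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  e$vectors %*% (log(e$values) * t(e$vectors))
}

.spdExp <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

#' ERP super-trial covariance
#'
#' Builds the classifier's feature matrix for one epoch: the ERP prototype
#' waveform is stacked over the epoch (2C x T rows), the sample covariance
#' across time is taken, and the result is shrunk toward a scaled identity,
#' `(1 - lambda) S + lambda * mean(diag(S)) I`, guaranteeing a symmetric
#' positive-definite output. The prototype rows make the covariance
#' sensitive to the epoch's temporal alignment with the average oddball
#' response, which is what separates single oddball epochs from standards.
#'
#' @param epoch Channels x time matrix (microvolts).
#' @param prototype Channels x time prototype waveform, same shape.
#' @param shrinkage Shrinkage weight lambda in \[0, 1\] (default 0.1).
#' @return 2C x 2C SPD matrix.
#' @export
erpSuperTrialCovariance <- function(epoch, prototype, shrinkage = 0.1) {
  stopIf(!all(dim(epoch) == dim(prototype)),
         "epoch and prototype must share one shape")
  stopIf(shrinkage < 0 || shrinkage > 1, "'shrinkage' must be in [0, 1]")
  X <- rbind(prototype, epoch)
  d <- nrow(X)
  Tn <- ncol(X)
  stopIf(Tn < d && shrinkage == 0,
         paste0("covariance is rank-deficient (T = %d < 2C = %d); ",
                "set shrinkage > 0"), Tn, d)
  Xc <- X - rowMeans(X)
  S <- tcrossprod(Xc) / max(1L, Tn - 1L)
  scale <- mean(diag(S))
  if (scale <= 0) scale <- 1e-12   # degenerate all-zero input
  out <- (1 - shrinkage) * S + shrinkage * scale * diag(d)
  (out + t(out)) / 2
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' `d(A, B) = sqrt(sum(log(lambda_i)^2))` over the eigenvalues of
#' `A^(-1) B`, computed through the symmetric form
#' `A^(-1/2) B A^(-1/2)`. Invariant under congruence transforms
#' `d(G' A G, G' B G) = d(A, B)`.
#'
#' @param A,B SPD matrices of equal dimension.
#' @return Nonnegative scalar distance.
#' @examples
#' riemannianDistance(diag(4), exp(2) * diag(4))   # = 2 * sqrt(4) = 4
#' @export
riemannianDistance <- function(A, B) {
  .assertSpd(A, "'A'")
  .assertSpd(B, "'B'")
  stopIf(nrow(A) != nrow(B), "'A' and 'B' must share one dimension")
  W <- .spdPow(A, -0.5)
  M <- W %*% B %*% W
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(ev)^2))
}

#' Geometric (Karcher/Frechet) mean of SPD matrices
#'
#' Fixed-point iteration on the tangent-space average under the
#' affine-invariant metric: at the current estimate M, all matrices are
#' mapped to the tangent space at M, averaged, and the exponential map is
#' applied; iteration stops when the Frobenius norm of the tangent mean
#' falls below `tol`. Equivariant under congruence transforms; for
#' commuting matrices it reduces to the elementwise geometric mean.
#'
#' @param matrices Nonempty list of SPD matrices of equal dimension.
#' @param tol Convergence tolerance on the tangent-mean norm (default
#'   1e-8).
#' @param maxIter Iteration cap (default 50); non-convergence raises an
#'   error reporting the final norm.
#' @return The mean SPD matrix.
#' @examples
#' geometricMean(list(diag(c(1, 1)), diag(c(4, 9))))   # diag(2, 3)
#' @export
geometricMean <- function(matrices, tol = 1e-8, maxIter = 50L) {
  stopIf(!length(matrices), "'matrices' must be a nonempty list")
  for (A in matrices) .assertSpd(A, "input matrix")
  if (length(matrices) == 1L) return(matrices[[1L]])
  M <- Reduce(`+`, matrices) / length(matrices)
  for (it in seq_len(maxIter)) {
    W <- .spdPow(M, -0.5)
    Wi <- .spdPow(M, 0.5)
    Tm <- Reduce(`+`, lapply(matrices, function(A) .spdLog(W %*% A %*% W))) /
      length(matrices)
    nrm <- sqrt(sum(Tm^2))
    M <- Wi %*% .spdExp(Tm) %*% Wi
    M <- (M + t(M)) / 2
    if (nrm < tol) return(M)
  }
  stop(sprintf(
    "geometric mean did not converge in %d iterations (final norm %.3g)",
    maxIter, nrm), call. = FALSE)
}

# Covariance features for every epoch of an EpochSet, given a prototype.
.epochCovariances <- function(epochs, prototype, shrinkage) {
  lapply(seq_len(nEpochs(epochs)), function(e)
    erpSuperTrialCovariance(epochs@epochs[e, , , drop = TRUE], prototype,
                            shrinkage))
}

#' Fit a minimum-distance-to-means classifier
#'
#' The ERP prototype (mean of the training oddball epochs) is stacked over
#' every training epoch to form super-trial covariances; each class is
#' then summarized by the geometric (Karcher) mean of its covariances
#' under the affine-invariant metric, or by the arithmetic mean under the
#' Euclidean ablation.
#'
#' @param epochs Training [EpochSet-class].
#' @param labels Class label per epoch (default: the epoch labels).
#' @param metric `"riemannian"` (default) or `"euclidean"`.
#' @param shrinkage Covariance shrinkage lambda (default 0.1).
#' @return An [MdmModel-class].
#' @seealso [predictMdm()], [evaluateCv()]
#' @export
fitMdm <- function(epochs, labels = epochLabels(epochs),
                   metric = c("riemannian", "euclidean"), shrinkage = 0.1) {
  validObject(epochs)
  metric <- match.arg(metric)
  classes <- sort(unique(labels))
  stopIf(length(classes) < 2L,
         "training data contains a single class ('%s')", classes[1L])
  stopIf(min(table(labels)) < 2L, "need >= 2 epochs per class")
  protoClass <- if ("oddball" %in% classes) "oddball" else classes[1L]
  idx <- which(labels == protoClass)
  proto <- apply(epochs@epochs[idx, , , drop = FALSE], c(2L, 3L), mean)
  covs <- .epochCovariances(epochs, proto, shrinkage)
  means <- lapply(classes, function(cl) {
    cc <- covs[labels == cl]
    if (metric == "riemannian") geometricMean(cc)
    else Reduce(`+`, cc) / length(cc)
  })
  names(means) <- classes
  new("MdmModel", classes = classes, means = means, prototype = proto,
      metric = metric, shrinkage = shrinkage,
      channelNames = channelNames(epochs))
}

#' Predict epoch classes with a fitted MDM model
#'
#' Each epoch is assigned to the class whose mean covariance is nearest
#' (Riemannian or Euclidean/Frobenius distance, matching the model). The
#' continuous score is the distance difference
#' `d(x, mean_2) - d(x, mean_1)` over the lexicographically sorted classes
#' — with the default `oddball`/`standard` labels, larger scores mean more
#' oddball-like. Exact ties go to the first class and are flagged.
#'
#' @param model An [MdmModel-class].
#' @param epochs [EpochSet-class] to score (same channels as training).
#' @return data.frame with columns `label`, `score`, `tie`.
#' @export
predictMdm <- function(model, epochs) {
  validObject(model)
  validObject(epochs)
  stopIf(!identical(channelNames(epochs), model@channelNames),
         "channel mismatch between model (%s) and epochs (%s)",
         paste(model@channelNames, collapse = ","),
         paste(channelNames(epochs), collapse = ","))
  covs <- .epochCovariances(epochs, model@prototype, model@shrinkage)
  distFun <- if (model@metric == "riemannian") riemannianDistance
             else function(A, B) sqrt(sum((A - B)^2))
  D <- vapply(covs, function(C)
    vapply(model@means, function(M) distFun(C, M), numeric(1)),
    numeric(length(model@classes)))
  D <- matrix(D, nrow = length(model@classes))   # classes x epochs
  tie <- D[1L, ] == D[2L, ]
  label <- model@classes[apply(D, 2L, which.min)]  # which.min: first on tie
  data.frame(label = label, score = D[2L, ] - D[1L, ], tie = tie)
}

# Pearson chi-square statistic (no continuity correction) of a 2x2 table.
confusionChiSquare <- function(m) {
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(statistic = NA_real_, p = NA_real_))
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value)
}

# Rank-based AUC of `scores` for binary truth `positive` (logical).
.rankAuc <- function(scores, positive) {
  n1 <- sum(positive)
  n2 <- sum(!positive)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Cross-validated evaluation of the MDM classifier
#'
#' Stratified k-fold cross-validation: folds are drawn per class under the
#' seed, the model (including its ERP prototype) is refit on each training
#' split, and out-of-fold predictions are pooled into a single confusion
#' matrix. Reports accuracy, rank-based AUC of the distance-difference
#' score (positive class `oddball` when present), and the Pearson
#' chi-square test (no continuity correction) of the confusion table.
#'
#' @param epochs An [EpochSet-class].
#' @param labels Class label per epoch (default: the epoch labels); every
#'   class must have at least `kFolds` epochs.
#' @param kFolds Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @param metric,shrinkage Passed to [fitMdm()].
#' @return A [ClassifierReport-class].
#' @export
evaluateCv <- function(epochs, labels = epochLabels(epochs), kFolds = 5L,
                       seed = 1L, metric = c("riemannian", "euclidean"),
                       shrinkage = 0.1) {
  validObject(epochs)
  metric <- match.arg(metric)
  classes <- sort(unique(labels))
  stopIf(length(classes) != 2L, "need exactly two classes, got %d",
         length(classes))
  counts <- table(labels)
  stopIf(min(counts) < kFolds,
         "class '%s' has %d epochs, fewer than kFolds = %d",
         names(counts)[which.min(counts)], min(counts), kFolds)
  fold <- integer(length(labels))
  withSeed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(kFolds), length(idx)))
    }
  })
  truth <- character(0)
  pred <- character(0)
  scores <- numeric(0)
  for (k in seq_len(kFolds)) {
    tr <- fold != k
    trainSet <- new("EpochSet",
                    epochs = epochs@epochs[tr, , , drop = FALSE],
                    times = epochs@times, labels = labels[tr],
                    fs = epochs@fs, channelNames = epochs@channelNames)
    testSet <- new("EpochSet",
                   epochs = epochs@epochs[!tr, , , drop = FALSE],
                   times = epochs@times, labels = labels[!tr],
                   fs = epochs@fs, channelNames = epochs@channelNames)
    model <- fitMdm(trainSet, metric = metric, shrinkage = shrinkage)
    p <- predictMdm(model, testSet)
    truth <- c(truth, labels[!tr])
    pred <- c(pred, p$label)
    scores <- c(scores, p$score)
  }
  conf <- table(factor(truth, levels = classes),
                factor(pred, levels = classes))
  conf <- matrix(as.integer(conf), 2L, 2L,
                 dimnames = list(truth = classes, predicted = classes))
  positive <- truth == (if ("oddball" %in% classes) "oddball"
                        else classes[1L])
  cs <- confusionChiSquare(conf)
  new("ClassifierReport",
      accuracy = sum(diag(conf)) / sum(conf),
      auc = .rankAuc(scores, positive),
      confusion = conf, chisq = cs$statistic, pValue = cs$p,
      folds = as.integer(kFolds), seed = as.integer(seed))
}
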