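# SPD geometry oracles, super-trial covariances, MDM fit/predict, CV.

test_that("super-trial covariance has the documented block structure", {
  C <- 2; Tn <- 40
  set.seed(1)
  proto <- matrix(rnorm(C * Tn), C, Tn)

  # epoch == prototype, no shrinkage: all four C x C blocks identical
  S <- erpSuperTrialCovariance(proto, proto, shrinkage = 0)
  expect_equal(S[1:C, 1:C], S[1:C, C + 1:C])
  expect_equal(S[1:C, 1:C], S[C + 1:C, C + 1:C])

  # full shrinkage: scaled identity
  S1 <- erpSuperTrialCovariance(matrix(rnorm(C * Tn), C, Tn), proto,
                                shrinkage = 1)
  expect_equal(S1, diag(S1[1, 1], 2 * C))

  # zero epoch: the epoch-epoch block is exactly lambda * scale * I
  S0 <- erpSuperTrialCovariance(matrix(0, C, Tn), proto, shrinkage = 0.1)
  Xc <- rbind(proto, matrix(0, C, Tn))
  Xc <- Xc - rowMeans(Xc)
  scale <- mean(diag(tcrossprod(Xc) / (Tn - 1)))
  expect_equal(S0[C + 1:C, C + 1:C], diag(0.1 * scale, C),
               tolerance = 1e-12)

  expect_error(erpSuperTrialCovariance(matrix(0, 4, 6), matrix(0, 4, 6),
                                       shrinkage = 0), "rank-deficient")
})

test_that("Riemannian distance matches its closed forms and axioms", {
  expect_equal(riemannianDistance(diag(4), exp(2) * diag(4)), 4,
               tolerance = 1e-8)
  expect_equal(riemannianDistance(diag(c(1, 4)), diag(c(2, 2))),
               sqrt(2) * log(2), tolerance = 1e-8)
  A <- randomSpd(4, 1)
  B <- randomSpd(4, 2)
  expect_lt(riemannianDistance(A, A), 1e-7)
  expect_equal(riemannianDistance(A, B), riemannianDistance(B, A),
               tolerance = 1e-10)
  # congruence invariance
  set.seed(3)
  G <- matrix(rnorm(16), 4)
  expect_equal(riemannianDistance(t(G) %*% A %*% G, t(G) %*% B %*% G),
               riemannianDistance(A, B), tolerance = 1e-6)
  notSpd <- matrix(c(1, 2, 2, 1), 2)   # eigenvalues 3, -1
  expect_error(riemannianDistance(notSpd, diag(2)), "positive definite")
})

test_that("geometric mean: singleton, commuting case, equivariance, optimum", {
  A <- randomSpd(3, 4)
  expect_identical(geometricMean(list(A)), A)
  expect_equal(geometricMean(list(diag(c(1, 1)), diag(c(4, 9)))),
               diag(c(2, 3)), tolerance = 1e-6)

  ms <- lapply(5:9, function(s) randomSpd(4, s))
  M <- geometricMean(ms)
  set.seed(10)
  G <- matrix(rnorm(16), 4)
  M2 <- geometricMean(lapply(ms, function(X) t(G) %*% X %*% G))
  expect_equal(M2, t(G) %*% M %*% G, tolerance = 1e-6)

  # local minimality of the Frechet objective
  obj <- function(X) sum(vapply(ms, function(A)
    riemannianDistance(X, A)^2, numeric(1)))
  f0 <- obj(M)
  set.seed(11)
  for (k in 1:10) {
    S <- matrix(rnorm(16), 4); S <- (S + t(S)) / 2
    S <- 0.05 * S / sqrt(sum(S^2))
    W <- remoteEEG:::.spdPow(M, 0.5)
    X <- W %*% remoteEEG:::.spdExp(S) %*% W
    expect_gte(obj((X + t(X)) / 2), f0 - 1e-8)
  }
})

test_that("MDM fit and predict follow the distance rule and tie policy", {
  set.seed(2)
  mk <- function(e, scale) matrix(rnorm(2 * 48, sd = scale), 2, 48)
  labels <- rep(c("oddball", "standard"), each = 6)
  ep <- makeEpochSet(12, labels, function(e)
    mk(e, if (labels[e] == "oddball") 1 else 6))
  model <- fitMdm(ep)
  expect_identical(model@classes, c("oddball", "standard"))
  expect_gt(riemannianDistance(model@means[[1]], model@means[[2]]), 0)

  # euclidean metric: class mean is the arithmetic average
  mE <- fitMdm(ep, metric = "euclidean")
  covs <- remoteEEG:::.epochCovariances(ep, mE@prototype, 0.1)
  expect_equal(mE@means[["oddball"]],
               Reduce(`+`, covs[labels == "oddball"]) / 6,
               tolerance = 1e-12)

  # refit with permuted training order gives the same model
  perm <- withr::with_seed(5, sample(12))
  ep2 <- new("EpochSet", epochs = ep@epochs[perm, , , drop = FALSE],
             times = ep@times, labels = ep@labels[perm], fs = ep@fs,
             channelNames = ep@channelNames)
  m2 <- fitMdm(ep2)
  expect_equal(m2@means[["oddball"]], model@means[["oddball"]],
               tolerance = 1e-6)

  pr <- predictMdm(model, ep)
  expect_true(all(pr$label[1:6] == "oddball"))
  expect_true(all(pr$score[1:6] > 0))   # more oddball-like => positive

  expect_error(fitMdm(makeEpochSet(4, rep("a", 4), function(e) mk(e, 1))),
               "single class")
  epBad <- makeEpochSet(2, c("a", "b"), function(e) matrix(0, 3, 10),
                        channels = c("x", "y", "z"))
  expect_error(predictMdm(model, epBad), "channel mismatch")
})

test_that("prediction scores are invariant to a common channel mixing", {
  set.seed(7)
  labels <- rep(c("oddball", "standard"), each = 8)
  base <- lapply(1:16, function(e)
    matrix(rnorm(2 * 64, sd = if (labels[e] == "oddball") 1 else 3), 2, 64))
  epA <- makeEpochSet(16, labels, function(e) base[[e]])
  G <- matrix(c(2, 0.5, -0.3, 1), 2)
  epB <- makeEpochSet(16, labels, function(e) G %*% base[[e]])
  mA <- fitMdm(epA, shrinkage = 0)
  mB <- fitMdm(epB, shrinkage = 0)
  expect_equal(predictMdm(mB, epB)$score, predictMdm(mA, epA)$score,
               tolerance = 1e-6)
})

test_that("cross-validation separates separable classes and scores them", {
  set.seed(8)
  labels <- rep(c("oddball", "standard"), each = 15)
  ep <- makeEpochSet(30, labels, function(e)
    matrix(rnorm(2 * 64, sd = if (labels[e] == "oddball") 1 else 8), 2, 64))
  rep <- evaluateCv(ep, kFolds = 5, seed = 1)
  expect_identical(rep@accuracy, 1)
  expect_identical(rep@auc, 1)
  expect_identical(sum(rep@confusion), 30L)

  expect_error(evaluateCv(ep, kFolds = 20), "fewer than kFolds")
})

test_that("chi-square of the confusion table matches the closed form", {
  m <- matrix(c(45L, 5L, 5L, 45L), 2, byrow = TRUE)
  cs <- remoteEEG:::confusionChiSquare(m)
  expect_equal(cs$statistic, 64, tolerance = 1e-12)
  # cross-check against the textbook formula n(ad-bc)^2/(r1 r2 c1 c2)
  expect_equal(cs$statistic,
               100 * (45 * 45 - 5 * 5)^2 / (50 * 50 * 50 * 50))
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  set.seed(12)
  scores <- c(rnorm(40, 1), rnorm(60, 0))
  positive <- rep(c(TRUE, FALSE), c(40, 60))
  mine <- remoteEEG:::.rankAuc(scores, positive)
  refr <- as.numeric(pROC::auc(pROC::roc(response = positive,
                                         predictor = scores,
                                         quiet = TRUE,
                                         direction = "<")))
  expect_equal(mine, refr, tolerance = 1e-12)
})
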