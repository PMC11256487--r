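# ERP epoching, averaging, and the cluster-based permutation test,
# including agreement with an independent in-test implementation.

test_that("ERP epochs are extracted, baseline-corrected and counted", {
  cfg <- oddballConfig(nTrials = 200L, seed = 1L)
  rec <- simulateRecording(simulationPlan(cfg, seed = 1L))
  ep <- extractErpEpochs(rec)
  expect_identical(nEpochs(ep), 200L)
  expect_identical(dim(epochArray(ep))[3L],
                   as.integer(round((0.8 + 0.2) * 256)) + 1L)
  expect_setequal(unique(epochLabels(ep)), c("oddball", "standard"))

  # constant channel is identically zero after baseline correction
  flat <- rec
  flat@data[] <- 7
  epF <- extractErpEpochs(flat)
  expect_true(all(abs(epochArray(epF)) < 1e-12))

  # markers near the recording edge are dropped with a count
  early <- rec
  early@marker[] <- 0L
  early@marker[c(10L, 5000L)] <- c(2L, 1L)
  expect_message(epE <- extractErpEpochs(early), "dropped 1")
  expect_identical(nEpochs(epE), 1L)
  expect_identical(epE@metadata$dropped, 1L)

  none <- rec
  none@marker[] <- 0L
  expect_warning(ep0 <- extractErpEpochs(none), "no markers")
  expect_identical(nEpochs(ep0), 0L)
})

test_that("condition averages behave under symmetry and single epochs", {
  base <- matrix(rnorm(2 * 64), 2, 64)
  ep <- makeEpochSet(2, c("a", "a"),
                     function(e) if (e == 1) base else -base)
  av <- averageErp(ep)
  expect_true(all(abs(av$a$mean) < 1e-12))

  single <- makeEpochSet(2, c("a", "b"), function(e) base * e)
  # both conditions are singletons: one warning each
  expect_warning(expect_warning(avS <- averageErp(single), "single epoch"),
                 "single epoch")
  expect_equal(unname(avS$a$mean), base)
  expect_true(all(is.na(avS$a$se)))
})

test_that("cluster test finds no clusters in constant data and needs args", {
  ep <- makeEpochSet(8, rep(c("a", "b"), 4), function(e) matrix(0, 2, 32))
  res <- clusterPermutationTest(ep, "TP9", nPermutations = 100, seed = 1)
  expect_identical(nrow(res@clusters), 0L)
  expect_error(clusterPermutationTest(ep, "TP9", nPermutations = 0),
               "nPermutations")
  expect_error(clusterPermutationTest(ep, "nosuch"), "unknown channel")
})

test_that("observed clusters are invariant to epoch order", {
  set.seed(4)
  ep <- makeEpochSet(30, rep(c("oddball", "standard"), 15), function(e) {
    m <- matrix(rnorm(2 * 64), 2, 64)
    if (e %% 2 == 1) m[, 20:35] <- m[, 20:35] + 1.5
    m
  })
  res1 <- clusterPermutationTest(ep, "TP9", nPermutations = 200, seed = 9)
  perm <- withr::with_seed(1, sample(30))
  ep2 <- new("EpochSet", epochs = ep@epochs[perm, , , drop = FALSE],
             times = ep@times, labels = ep@labels[perm], fs = ep@fs,
             channelNames = ep@channelNames)
  res2 <- clusterPermutationTest(ep2, "TP9", nPermutations = 200, seed = 9)
  expect_identical(res1@clusters$startS, res2@clusters$startS)
  expect_identical(res1@clusters$endS, res2@clusters$endS)
  expect_equal(res1@clusters$mass, res2@clusters$mass)
  expect_gte(min(res1@clusters$p), 1 / 201)
})

# Independent reference implementation: explicit loops, textbook pooled-t,
# rle-based clustering, its own permutation draw.
referenceClusterTest <- function(X, labels, alpha, nPerm, seed) {
  tAt <- function(x1, x2) {
    n1 <- length(x1); n2 <- length(x2)
    sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
    (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  conds <- sort(unique(labels))
  thr <- qt(1 - alpha / 2, df = length(labels) - 2)
  tv <- sapply(seq_len(ncol(X)), function(j)
    tAt(X[labels == conds[1], j], X[labels == conds[2], j]))
  clus <- function(tv) {
    r <- rle(abs(tv) > thr)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    k <- which(r$values)
    if (!length(k)) return(NULL)
    data.frame(start = starts[k], end = ends[k],
               mass = sapply(k, function(i)
                 sum(abs(tv[starts[i]:ends[i]]))))
  }
  obs <- clus(tv)
  set.seed(seed + 1000)
  nullMax <- replicate(nPerm, {
    lp <- sample(labels)
    tp <- sapply(seq_len(ncol(X)), function(j)
      tAt(X[lp == conds[1], j], X[lp == conds[2], j]))
    cp <- clus(tp)
    if (is.null(cp)) 0 else max(cp$mass)
  })
  if (is.null(obs)) return(obs)
  obs$p <- sapply(obs$mass, function(m)
    (1 + sum(nullMax >= m)) / (nPerm + 1))
  obs
}

test_that("cluster test agrees with an independent implementation", {
  set.seed(11)
  n <- 16
  labels <- rep(c("oddball", "standard"), each = n / 2)
  ep <- makeEpochSet(n, labels, function(e) {
    m <- matrix(rnorm(2 * 48, sd = 1), 2, 48)
    if (labels[e] == "oddball") m[, 15:25] <- m[, 15:25] + 1.6
    m
  })
  X <- ep@epochs[, 1, ]
  ref <- referenceClusterTest(X, labels, alpha = 0.05, nPerm = 2000,
                              seed = 5)
  res <- clusterPermutationTest(ep, "TP9", clusterFormingP = 0.05,
                                nPermutations = 2000, seed = 5)
  # identical cluster boundaries and masses
  expect_equal(as.integer(round(res@clusters$startS * ep@fs)) + 1L,
               ref$start)
  expect_equal(as.integer(round(res@clusters$endS * ep@fs)) + 1L,
               ref$end)
  expect_equal(res@clusters$mass, ref$mass, tolerance = 1e-10)
  # p within Monte-Carlo tolerance at matched permutation counts
  expect_equal(res@clusters$p, ref$p, tolerance = 0.1)
  expect_lt(max(abs(res@clusters$p - ref$p)), 0.05)
})

test_that("an injected sustained effect is recovered as a low-p cluster", {
  tpl <- erpTemplate(data.frame(latencyS = 0.325, widthS = 0.0375,
                                amplitudeUv = 5, polarity = "+"))
  cfg <- oddballConfig(nTrials = 400L, seed = 3L)
  rec <- bandpass(simulateRecording(simulationPlan(cfg,
                                                   oddballTemplate = tpl,
                                                   seed = 3L)))
  ep <- extractErpEpochs(rec)
  res <- clusterPermutationTest(ep, "TP9", nPermutations = 1000, seed = 3)
  cl <- res@clusters
  hit <- cl[cl$startS <= 0.40 & cl$endS >= 0.25, ]
  expect_gte(nrow(hit), 1L)
  expect_lte(min(hit$p), 0.01)
})
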