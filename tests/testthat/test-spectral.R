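# Bandpass contract, rest epoching, relative band powers, alpha blocking,
# band-change table.

mkSineRecording <- function(freq, ampl = 10, durS = 8, fs = 256) {
  t <- (0:(durS * fs - 1)) / fs
  dat <- matrix(rep(ampl * sin(2 * pi * freq * t), 4), nrow = 4,
                byrow = TRUE,
                dimnames = list(c("TP9", "AF7", "AF8", "TP10"), NULL))
  new("EEGRecording", timestamps = t, data = dat,
      marker = integer(length(t)), device = getDeviceSpec("virtual"))
}

test_that("bandpass keeps the passband and strongly attenuates mains", {
  inner <- function(rec) {
    n <- nSamples(rec)
    idx <- round(n / 4):round(3 * n / 4)  # avoid edges
    sd(eegData(rec)["TP9", idx])
  }
  r10 <- mkSineRecording(10)
  r60 <- mkSineRecording(60)
  g10 <- inner(bandpass(r10)) / inner(r10)
  expect_equal(g10, 1, tolerance = 0.05)
  att <- 20 * log10(inner(bandpass(r10)) / inner(bandpass(r60)))
  expect_gte(att, 20)

  zero <- mkSineRecording(10, ampl = 0)
  expect_true(all(eegData(bandpass(zero)) == 0))

  expect_error(bandpass(r10, hiHz = 130), "Nyquist")

  # idempotent within tolerance on an already band-limited signal
  once <- bandpass(r10)
  twice <- bandpass(once)
  expect_equal(inner(twice) / inner(once), 1, tolerance = 0.02)
})

test_that("rest segmentation yields floor(duration / epoch) labeled epochs", {
  cfg <- restConfig(closedS = 60, openS = 60)
  rec <- simulateRecording(simulationPlan(cfg))
  ep <- segmentRest(rec)
  expect_identical(nEpochs(ep), 60L)
  expect_identical(sum(epochLabels(ep) == "eyes_closed"), 30L)

  short <- segmentRest(rec, data.frame(startS = 0, endS = 3.5,
                                       condition = "eyes_closed"))
  expect_identical(nEpochs(short), 1L)
  none <- segmentRest(rec, data.frame(startS = numeric(),
                                      endS = numeric(),
                                      condition = character()))
  expect_identical(nEpochs(none), 0L)
})

test_that("relative band powers concentrate, normalize and scale-invariate", {
  fs <- 256
  t <- (0:(2 * fs - 1)) / fs
  alpha <- relativeBandPowers(sin(2 * pi * 10 * t), fs)
  expect_gt(alpha[["alpha"]], 0.9)
  expect_equal(sum(alpha), 1, tolerance = 1e-9)

  set.seed(2)
  x <- rnorm(2 * fs)
  p1 <- relativeBandPowers(x, fs)
  expect_equal(sum(p1), 1, tolerance = 1e-9)
  expect_equal(p1, relativeBandPowers(1000 * x, fs),
               tolerance = 1e-12)

  # white noise: each band's share ~ its width / 54
  w <- genColoredNoise(2^14, fs, noiseSpec(10, spectralExponent = 0),
                       seed = 5)
  pw <- relativeBandPowers(w, fs)
  bands <- defaultBands()
  expected <- (bands$hiHz - bands$loHz) / 54
  expect_true(all(abs(pw - expected) / expected < 0.2))

  expect_error(relativeBandPowers(rnorm(100), fs), "at least 1 s")
})

test_that("alpha blocking is detected with the documented sign convention", {
  cfg <- restConfig(closedS = 60, openS = 60, seed = 2L)
  rec <- simulateRecording(simulationPlan(cfg, seed = 2L))
  res <- analyzeAlphaBlocking(rec)
  expect_gt(res$meanDifference, 0)     # closed > open
  expect_lt(res$p, 1e-4)
  expect_identical(c(res$nClosed, res$nOpen), c(30L, 30L))

  # antisymmetry under label swap
  tab <- bandPowerTable(segmentRest(bandpass(rec)), channels = "TP9")
  closed <- tab[tab$condition == "eyes_closed", ]
  open <- tab[tab$condition == "eyes_open", ]
  fwd <- alphaBlockingTest(closed, open)
  rev <- alphaBlockingTest(open, closed)
  expect_equal(rev$t, -fwd$t)
  expect_equal(rev$p, fwd$p)

  deg <- alphaBlockingTest(c(0.5, 0.5), c(0.5, 0.5))
  expect_true(deg$degenerate)
  expect_identical(deg$p, 1)
  expect_identical(deg$meanDifference, 0)

  expect_error(alphaBlockingTest(0.5, c(0.4, 0.4)), "2 epochs")
})

test_that("band-change table flags the alpha effect and only that effect", {
  sessions <- lapply(1:3, function(s)
    simulateRecording(simulationPlan(restConfig(60, 60, seed = s),
                                     seed = s)))
  tab <- bandChangeTable(sessions)
  expect_identical(nrow(tab), 4L * 5L)
  expect_identical(tab$channel[1:2], c("TP9", "TP10"))  # symmetric pairs

  alphaRows <- tab[tab$band == "alpha", ]
  expect_true(all(alphaRows$pAdjusted < 0.05))
  expect_true(all(alphaRows$t > 0))
  deltaRows <- tab[tab$band == "delta", ]
  expect_true(all(deltaRows$meanClosed > 0))

  expect_error(
    bandChangeTable(list(simulateRecording(simulationPlan(
      sessionConfig(list(taskSpec("rest_eyes_open", durationS = 10))))))),
    "both rest conditions")
})

test_that("no-effect sessions rarely reach adjusted significance", {
  # alpha gain 1 in both states: null across all channel x band cells
  osc <- list(oscillationSpec(10, 5, c(eyes_open = 1, eyes_closed = 1)))
  hits <- vapply(1:6, function(s) {
    rec <- simulateRecording(simulationPlan(restConfig(30, 30, seed = s),
                                            oscillations = osc, seed = s))
    any(bandChangeTable(list(rec))$pAdjusted < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 1 / 3)
})
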