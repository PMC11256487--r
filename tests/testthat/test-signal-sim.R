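# Virtual-device simulator: colored noise, state-gated oscillations,
# ERP templates, full-session rendering.

test_that("colored noise has the requested RMS, determinism and spectrum", {
  expect_identical(genColoredNoise(100, 256, noiseSpec(0), seed = 1),
                   numeric(100))
  a <- genColoredNoise(4096, 256, noiseSpec(10), seed = 7)
  b <- genColoredNoise(4096, 256, noiseSpec(10), seed = 7)
  expect_identical(a, b)
  expect_lt(abs(sqrt(mean(a^2)) - 10) / 10, 0.2)

  # log-log periodogram slope of 1/f noise over 2-50 Hz
  x <- genColoredNoise(2^16, 256, noiseSpec(10, spectralExponent = 1),
                       seed = 3)
  sp <- stats::spec.pgram(stats::ts(x, frequency = 256), plot = FALSE,
                          taper = 0)
  keep <- sp$freq >= 2 & sp$freq <= 50
  slope <- unname(stats::coef(
    stats::lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[2L])
  expect_gt(slope, -1.3)
  expect_lt(slope, -0.7)

  expect_error(genColoredNoise(1, 256, noiseSpec()), "nSamples")
  expect_error(genColoredNoise(100, -1, noiseSpec()), "fs")
})

test_that("oscillations are added only inside their state intervals", {
  fs <- 256
  zero <- numeric(8 * fs)
  spec <- oscillationSpec(10, 10, c(eyes_open = 1, eyes_closed = 2))
  tl <- data.frame(startS = c(0, 4), endS = c(4, 8),
                   state = c("eyes_closed", "eyes_open"))
  y <- addOscillation(zero, fs, spec, tl)
  # closed-interval variance ~ 4x the open-interval variance
  vClosed <- var(y[1:(4 * fs)])
  vOpen <- var(y[(4 * fs + 1):(8 * fs)])
  expect_equal(vClosed / vOpen, 4, tolerance = 1e-6)
  # spectral peak at the bin nearest 10 Hz
  seg <- y[(4 * fs + 1):(8 * fs)]
  p <- Mod(fft(seg))^2
  freqs <- (seq_along(seg) - 1) * fs / length(seg)
  half <- freqs < fs / 2
  expect_equal(freqs[half][which.max(p[half])], 10, tolerance = fs / length(seg))

  # zero amplitude leaves the trace unchanged; outside intervals untouched
  expect_identical(addOscillation(zero, fs, oscillationSpec(10, 0), tl), zero)
  y2 <- addOscillation(zero, fs, spec,
                       data.frame(startS = 1, endS = 2, state = "eyes_open"))
  expect_identical(y2[1:fs], numeric(fs))
  expect_false(all(y2[(fs + 1):(2 * fs)] == 0))

  expect_error(addOscillation(zero, fs, oscillationSpec(200, 5), tl),
               "Nyquist")
  expect_error(
    addOscillation(zero, fs, spec,
                   data.frame(startS = c(0, 1), endS = c(2, 3),
                              state = "eyes_open")),
    "overlap")
})

test_that("ERP templates render as signed Gaussian bumps", {
  fs <- 256
  empty <- renderErp(erpTemplate(), fs, c(0, 0.8))
  expect_true(all(empty == 0))

  one <- erpTemplate(data.frame(latencyS = 0.3, widthS = 0.05,
                                amplitudeUv = 5, polarity = "+"),
                     channelGains = c(TP9 = 1))
  w <- renderErp(one, fs, c(0, 0.8))
  i <- which.min(abs(attr(w, "times") - 0.3))
  expect_equal(unname(w["TP9", i]), 5, tolerance = 1e-3)

  both <- defaultOddballTemplate()
  w2 <- renderErp(both, fs, c(0, 0.8))
  t2 <- attr(w2, "times")
  expect_lt(w2["TP9", which.min(abs(t2 - 0.2))], 0)
  expect_gt(w2["TP9", which.min(abs(t2 - 0.3))], 0)

  expect_error(renderErp(both, fs, c(0.5, 0.1)), "tmin")
})

test_that("simulated recordings are deterministic with conserved markers", {
  cfg <- oddballConfig(nTrials = 200L, seed = 1L)
  plan <- simulationPlan(cfg, seed = 1L)
  rec1 <- simulateRecording(plan)
  rec2 <- simulateRecording(plan)
  expect_identical(eegData(rec1), eegData(rec2))
  expect_identical(markers(rec1), markers(rec2))

  mk <- markers(rec1)
  expect_identical(sum(mk %in% c(1L, 2L)), 200L)
  seq1 <- buildOddballSequence(200, 0.1,
                               seed = remoteEEG:::deriveSeed(1L, 1L))
  expect_identical(sum(mk == 2L), sum(seq1 == "oddball"))

  # timestamps strictly increasing with spacing 1/fs
  expect_true(all(abs(diff(timestamps(rec1)) - 1 / 256) < 1e-12))

  # rest-only session: only task boundary codes
  rcfg <- sessionConfig(list(taskSpec("rest_eyes_open", durationS = 60)))
  rrec <- simulateRecording(simulationPlan(rcfg))
  expect_identical(sort(unique(markers(rrec)[markers(rrec) > 0])),
                   c(101L, 201L))

  # over-long sessions are refused
  longCfg <- sessionConfig(list(taskSpec("free_recording",
                                         durationS = 7200)))
  expect_error(simulateRecording(simulationPlan(longCfg)), "maximum")
})

test_that("stimulus-locked averages recover the injected template", {
  tpl <- erpTemplate(data.frame(latencyS = 0.3, widthS = 0.05,
                                amplitudeUv = 5, polarity = "+"))
  cfg <- oddballConfig(nTrials = 500L, pOddball = 0.5, seed = 4L)
  rec <- simulateRecording(simulationPlan(cfg, oddballTemplate = tpl,
                                          seed = 4L))
  ep <- extractErpEpochs(rec, baseline = NULL)
  av <- averageErp(ep)
  i <- which.min(abs(epochTimes(ep) - 0.3))
  diff <- unname(av$oddball$mean["TP9", i] -
                 av$standard$mean["TP9", i])
  expect_equal(diff, 5, tolerance = 1 / 5)  # ~ +-1 uV at this n and noise
})

test_that("doubling the template amplitude doubles the average difference", {
  mkPlan <- function(amp) {
    tpl <- erpTemplate(data.frame(latencyS = 0.3, widthS = 0.05,
                                  amplitudeUv = amp, polarity = "+"))
    simulationPlan(oddballConfig(nTrials = 200L, pOddball = 0.5, seed = 6L),
                   oddballTemplate = tpl, seed = 6L)
  }
  dAt <- function(plan) {
    ep <- extractErpEpochs(simulateRecording(plan), baseline = NULL)
    av <- averageErp(ep)
    i <- which.min(abs(epochTimes(ep) - 0.3))
    unname(av$oddball$mean["TP9", i] - av$standard$mean["TP9", i])
  }
  d1 <- dAt(mkPlan(5))
  d2 <- dAt(mkPlan(10))
  # matched noise (same seed): the difference of differences is the
  # injected 5 uV bump evaluated at the sample nearest 0.3 s
  expect_equal(d2 - d1, 5, tolerance = 1e-2)
})
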