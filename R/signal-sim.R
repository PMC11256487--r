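# Virtual wearable-EEG signal simulator: colored background noise,
# state-dependent oscillations, Gaussian-bump ERP templates, and the full
# session renderer that composes them into an EEGRecording.

#' Construct a background-noise specification
#'
#' @param amplitudeUv Target RMS of the 1/f^a background, microvolts
#'   (default 10, a conventional clean-scalp amplitude).
#' @param spectralExponent Power-law exponent a (default 1, pink noise).
#' @param lineNoiseUv Peak amplitude of the mains sinusoid, microvolts
#'   (default 0).
#' @param lineFreqHz Mains frequency, Hz (default 60).
#' @return A [NoiseSpec-class].
#' @examples
#' noiseSpec(amplitudeUv = 10)
#' @export
noiseSpec <- function(amplitudeUv = 10, spectralExponent = 1,
                      lineNoiseUv = 0, lineFreqHz = 60) {
  new("NoiseSpec", amplitudeUv = amplitudeUv,
      spectralExponent = spectralExponent,
      lineNoiseUv = lineNoiseUv, lineFreqHz = lineFreqHz)
}

#' Construct an oscillation specification
#'
#' @param centerFreqHz Oscillation frequency, Hz (default 10, mid-alpha).
#' @param amplitudeUv Baseline peak amplitude, microvolts (default 5).
#' @param stateGain Named multipliers per behavioral state; the default
#'   doubles the rhythm when the eyes are closed, the alpha-blocking
#'   contrast.
#' @return An [OscillationSpec-class].
#' @examples
#' oscillationSpec(10, 5, c(eyes_open = 1, eyes_closed = 2))
#' @export
oscillationSpec <- function(centerFreqHz = 10, amplitudeUv = 5,
                            stateGain = c(eyes_open = 1, eyes_closed = 2)) {
  new("OscillationSpec", centerFreqHz = centerFreqHz,
      amplitudeUv = amplitudeUv, stateGain = stateGain)
}

#' Construct an ERP template
#'
#' @param components data.frame with columns `latencyS`, `widthS`,
#'   `amplitudeUv`, `polarity` (`"+"`/`"-"`); zero rows give a null
#'   template.
#' @param channelGains Named per-channel multipliers (default: gain 1 on
#'   the four default wearable channels).
#' @return An [ErpTemplate-class].
#' @examples
#' # N200 + P300 oddball response
#' erpTemplate(data.frame(latencyS = c(0.2, 0.3), widthS = c(0.03, 0.05),
#'                        amplitudeUv = c(3, 5), polarity = c("-", "+")))
#' @export
erpTemplate <- function(components = data.frame(latencyS = numeric(),
                                                widthS = numeric(),
                                                amplitudeUv = numeric(),
                                                polarity = character()),
                        channelGains = c(TP9 = 1, AF7 = 1, AF8 = 1,
                                         TP10 = 1)) {
  new("ErpTemplate", components = components, channelGains = channelGains)
}

#' Default oddball ERP template (N200 + P300)
#'
#' A negative 3 uV deflection peaking 200 ms post-stimulus and a positive
#' 5 uV deflection peaking at 300 ms, on all four channels — the canonical
#' oddball response shape the analysis pipeline is validated against.
#'
#' @param channelGains Named per-channel multipliers.
#' @return An [ErpTemplate-class].
#' @export
defaultOddballTemplate <- function(channelGains = c(TP9 = 1, AF7 = 1,
                                                    AF8 = 1, TP10 = 1)) {
  erpTemplate(
    data.frame(latencyS = c(0.2, 0.3), widthS = c(0.03, 0.05),
               amplitudeUv = c(3, 5), polarity = c("-", "+")),
    channelGains = channelGains
  )
}

#' Construct a simulation plan
#'
#' @param session A [SessionConfig-class] (default [defaultSessionConfig()]).
#' @param noise A [NoiseSpec-class].
#' @param oscillations List of [OscillationSpec-class] objects (default: one
#'   state-dependent alpha rhythm).
#' @param oddballTemplate ERP template injected at oddball onsets (default
#'   [defaultOddballTemplate()]).
#' @param standardTemplate ERP template injected at standard onsets
#'   (default: empty, no deflection).
#' @param seed Master seed (default: the session config's seed).
#' @param maxDurationS Sessions longer than this are refused (default 3600).
#' @return A [SimulationPlan-class].
#' @seealso [simulateRecording()]
#' @export
simulationPlan <- function(session = defaultSessionConfig(),
                           noise = noiseSpec(),
                           oscillations = list(oscillationSpec()),
                           oddballTemplate = defaultOddballTemplate(),
                           standardTemplate = erpTemplate(),
                           seed = session@seed,
                           maxDurationS = 3600) {
  new("SimulationPlan", session = session, noise = noise,
      oscillations = oscillations, oddballTemplate = oddballTemplate,
      standardTemplate = standardTemplate, seed = as.integer(seed),
      maxDurationS = maxDurationS)
}

#' Generate colored (1/f^a) background noise
#'
#' Spectral shaping of Gaussian white noise: the FFT of a white draw is
#' multiplied by f^(-a/2) (zero at DC) and inverted, then the trace is
#' rescaled to the target RMS exactly. A mains sinusoid with random phase
#' is added when `spec@lineNoiseUv > 0`. Deterministic given `seed`.
#'
#' @param nSamples Number of samples (>= 2).
#' @param fs Sampling rate, Hz.
#' @param spec A [NoiseSpec-class].
#' @param seed Integer seed.
#' @return Numeric vector of length `nSamples` (microvolts).
#' @examples
#' x <- genColoredNoise(1024, 256, noiseSpec(10), seed = 1)
#' sd(x)   # ~10 uV
#' @export
genColoredNoise <- function(nSamples, fs, spec = noiseSpec(), seed = 1L) {
  stopIf(length(nSamples) != 1L || is.na(nSamples) || nSamples < 2L,
         "'nSamples' must be a single integer >= 2")
  stopIf(length(fs) != 1L || is.na(fs) || fs <= 0,
         "'fs' must be a single positive number")
  validObject(spec)
  n <- as.integer(nSamples)
  withSeed(seed, {
    x <- numeric(n)
    if (spec@amplitudeUv > 0) {
      white <- stats::rnorm(n)
      k <- 0:(n - 1L)
      fbin <- pmin(k, n - k) * fs / n  # two-sided frequency magnitude
      h <- c(0, fbin[-1L]^(-spec@spectralExponent / 2))
      x <- Re(stats::fft(stats::fft(white) * h, inverse = TRUE)) / n
      r <- sqrt(mean(x^2))
      if (r > 0) x <- x * (spec@amplitudeUv / r)
    }
    if (spec@lineNoiseUv > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      t <- (seq_len(n) - 1L) / fs
      x <- x + spec@lineNoiseUv * sin(2 * pi * spec@lineFreqHz * t + phase)
    }
    x
  })
}

#' Add a state-gated oscillation to a trace
#'
#' Adds `amplitudeUv * stateGain[state] * sin(2 pi f t + phase)` within each
#' listed state interval; the trace is untouched outside the intervals. The
#' phase argument is continuous in absolute time, so adjacent intervals
#' join without discontinuity.
#'
#' @param trace Single-channel numeric vector (microvolts).
#' @param fs Sampling rate, Hz.
#' @param spec An [OscillationSpec-class].
#' @param stateTimeline data.frame with columns `startS`, `endS`, `state`;
#'   intervals must be non-overlapping and inside the trace duration.
#'   States absent from `spec@stateGain` get gain 1.
#' @param phase Phase offset in radians (default 0).
#' @return The trace with the oscillation added.
#' @export
addOscillation <- function(trace, fs, spec, stateTimeline, phase = 0) {
  validObject(spec)
  stopIf(spec@centerFreqHz >= fs / 2,
         "'centerFreqHz' (%g) must be below the Nyquist frequency (%g)",
         spec@centerFreqHz, fs / 2)
  tl <- stateTimeline
  stopIf(!all(c("startS", "endS", "state") %in% names(tl)),
         "stateTimeline needs columns startS, endS, state")
  dur <- length(trace) / fs
  tl <- tl[order(tl$startS), , drop = FALSE]
  stopIf(any(tl$startS < 0) || any(tl$endS > dur + 1e-9),
         "state intervals must lie within the trace duration")
  if (nrow(tl) > 1L)
    stopIf(any(tl$startS[-1L] < tl$endS[-nrow(tl)] - 1e-9),
           "state intervals must not overlap")
  t <- (seq_along(trace) - 1L) / fs
  for (i in seq_len(nrow(tl))) {
    g <- spec@stateGain[[tl$state[i]]]
    if (is.null(g) || is.na(g)) g <- 1
    idx <- which(t >= tl$startS[i] - 1e-12 & t < tl$endS[i] - 1e-12)
    if (length(idx))
      trace[idx] <- trace[idx] +
        spec@amplitudeUv * g * sin(2 * pi * spec@centerFreqHz * t[idx] + phase)
  }
  trace
}

#' Render an ERP template as a per-channel waveform matrix
#'
#' Evaluates the sum of signed Gaussian bumps on a regular time grid:
#' component value `polarity * amplitudeUv * channelGain *
#' exp(-(t - latency)^2 / (2 width^2))`.
#'
#' @param template An [ErpTemplate-class].
#' @param fs Sampling rate, Hz.
#' @param window Length-2 numeric `(tminS, tmaxS)` with `tmin < tmax`.
#' @return Channels x time matrix (microvolts); rownames are the channels
#'   of `template@channelGains`, with a `"times"` attribute.
#' @examples
#' w <- renderErp(defaultOddballTemplate(), 256, c(0, 0.8))
#' @export
renderErp <- function(template, fs, window = c(0, 0.8)) {
  validObject(template)
  stopIf(length(window) != 2L || window[1L] >= window[2L],
         "'window' must be (tmin, tmax) with tmin < tmax")
  times <- seq(window[1L], window[2L], by = 1 / fs)
  chans <- names(template@channelGains)
  out <- matrix(0, nrow = length(chans), ncol = length(times),
                dimnames = list(chans, NULL))
  comp <- template@components
  if (nrow(comp)) {
    base <- numeric(length(times))
    for (i in seq_len(nrow(comp))) {
      sgn <- if (comp$polarity[i] == "+") 1 else -1
      base <- base + sgn * comp$amplitudeUv[i] *
        exp(-(times - comp$latencyS[i])^2 / (2 * comp$widthS[i]^2))
    }
    for (c in seq_along(chans))
      out[c, ] <- base * template@channelGains[[c]]
  }
  attr(out, "times") <- times
  out
}

#' Simulate a complete wearable-EEG session
#'
#' Renders the full recording a virtual device would produce under a
#' session configuration: per-channel 1/f background noise (independent
#' across channels), state-gated oscillations following the behavioral
#' timeline implied by the task sequence, ERP templates added at each
#' stimulus onset (oddball and, optionally, standard), and the marker
#' channel carrying one code per scheduled event at the sample nearest its
#' onset. Fully reproducible: identical plans give bitwise-identical
#' recordings.
#'
#' @param plan A [SimulationPlan-class].
#' @return An [EEGRecording-class].
#' @examples
#' rec <- simulateRecording(simulationPlan(seed = 1))
#' rec
#' @export
simulateRecording <- function(plan) {
  validObject(plan)
  config <- plan@session
  dev <- getDeviceSpec(config@device)
  fs <- dev@samplingRate
  sched <- scheduleSession(config)
  stopIf(sched$durationS > plan@maxDurationS,
         "session duration %.1f s exceeds the maximum %.1f s",
         sched$durationS, plan@maxDurationS)
  n <- as.integer(round(sched$durationS * fs))
  stopIf(n < 2L, "session too short to simulate")
  ts <- (seq_len(n) - 1L) / fs
  chans <- dev@channelNames
  dat <- matrix(0, nrow = length(chans), ncol = n,
                dimnames = list(chans, NULL))

  for (ci in seq_along(chans)) {
    tr <- genColoredNoise(n, fs, plan@noise,
                          seed = deriveSeed(plan@seed, ci))
    for (oi in seq_along(plan@oscillations)) {
      ph <- withSeed(deriveSeed(plan@seed, 1000L + 100L * oi + ci),
                     stats::runif(1, 0, 2 * pi))
      tr <- addOscillation(tr, fs, plan@oscillations[[oi]],
                           sched$stateTimeline, phase = ph)
    }
    dat[ci, ] <- tr
  }

  # stimulus-locked template injection
  injectTemplate <- function(dat, template, onsets) {
    if (!length(onsets) || !nrow(template@components)) return(dat)
    wmax <- max(template@components$latencyS +
                  4 * template@components$widthS)
    wave <- renderErp(template, fs, c(0, wmax))
    L <- ncol(wave)
    tchans <- intersect(rownames(wave), rownames(dat))
    for (on in onsets) {
      i0 <- round(on * fs) + 1L
      idx <- i0:min(i0 + L - 1L, n)
      dat[tchans, idx] <- dat[tchans, idx, drop = FALSE] +
        wave[tchans, seq_along(idx), drop = FALSE]
    }
    dat
  }
  ev <- sched$events
  dat <- injectTemplate(dat, plan@oddballTemplate,
                        ev$onsetS[ev$identity == "oddball"])
  dat <- injectTemplate(dat, plan@standardTemplate,
                        ev$onsetS[ev$identity == "standard"])

  marker <- placeMarkers(ev, ts)
  new("EEGRecording", timestamps = ts, data = dat, marker = marker,
      device = dev, session = config,
      metadata = list(simulated = TRUE, seed = plan@seed,
                      noiseRmsUv = plan@noise@amplitudeUv))
}
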