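#' @import methods
NULL

# ---------------------------------------------------------------------------
# Device / acquisition classes
# ---------------------------------------------------------------------------

#' Device specification
#'
#' Immutable description of a supported EEG wearable: its ordered electrode
#' montage, sampling rate and reference electrode position (10-20 system).
#' Instances are normally obtained from the device registry via
#' [getDeviceSpec()], not constructed directly.
#'
#' @slot name Registry identifier, e.g. `"muse2"` or `"virtual"`.
#' @slot channelNames Ordered electrode labels (unique).
#' @slot samplingRate Sampling rate in Hz (> 0).
#' @slot reference 10-20 label of the reference position, e.g. `"Fpz"`.
#' @slot provisional Logical; `TRUE` when the montage is not fully documented
#'   by the vendor and should be treated as a placeholder.
#'
#' @seealso [getDeviceSpec()], [listDevices()]
#' @export
setClass("DeviceSpec",
  representation(
    name = "character",
    channelNames = "character",
    samplingRate = "numeric",
    reference = "character",
    provisional = "logical"
  ),
  prototype(provisional = FALSE)
)

setValidity("DeviceSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "'samplingRate' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Chunk of streamed samples
#'
#' The unit of data handed from an acquisition backend to consumers: a block
#' of consecutive samples with strictly increasing timestamps. The replay
#' backend ([streamRecording()]) produces these; [assessQuality()] and
#' [runSession()] consume them.
#'
#' @slot timestamps Sample times in seconds, strictly increasing.
#' @slot samples Channels x n matrix of voltages (microvolts); rownames are
#'   channel labels.
#' @export
setClass("StreamChunk",
  representation(timestamps = "numeric", samples = "matrix")
)

setValidity("StreamChunk", function(object) {
  msg <- character()
  if (ncol(object@samples) != length(object@timestamps))
    msg <- c(msg, "number of sample columns must equal number of timestamps")
  if (length(object@timestamps) > 1L && any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Electrode signal-quality status
#'
#' Result of the pre-session quality gate: a per-electrode variability
#' estimate (rolling standard deviation in microvolts) and the derived
#' three-state classification used as traffic-light feedback (accepted /
#' near / rejected). The session may start only when `allAccepted` is TRUE.
#'
#' @slot variability Named per-electrode standard deviation (microvolts).
#' @slot state Named per-electrode state, one of `"accepted"`, `"near"`,
#'   `"rejected"`.
#' @slot allAccepted TRUE iff every electrode is `"accepted"`.
#' @slot acceptThreshold,rejectThreshold The thresholds (microvolts) the
#'   states were derived from.
#' @seealso [assessQuality()]
#' @export
setClass("QualityStatus",
  representation(
    variability = "numeric",
    state = "character",
    allAccepted = "logical",
    acceptThreshold = "numeric",
    rejectThreshold = "numeric"
  )
)

setValidity("QualityStatus", function(object) {
  msg <- character()
  if (length(object@state) != length(object@variability))
    msg <- c(msg, "'state' and 'variability' must have equal length")
  if (!all(object@state %in% c("accepted", "near", "rejected")))
    msg <- c(msg, "states must be 'accepted', 'near' or 'rejected'")
  if (length(object@allAccepted) != 1L)
    msg <- c(msg, "'allAccepted' must be a single logical")
  else if (object@allAccepted != all(object@state == "accepted"))
    msg <- c(msg, "'allAccepted' must equal all(state == 'accepted')")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Session configuration
# ---------------------------------------------------------------------------

#' Task specification
#'
#' One entry of a session's ordered task list. Rest and free-recording tasks
#' are described by a duration; oddball tasks by a trial count, oddball
#' probability, inter-stimulus interval and stimulus duration.
#'
#' @slot kind One of `"rest_eyes_open"`, `"rest_eyes_closed"`,
#'   `"free_recording"`, `"oddball"`.
#' @slot durationS Task duration in seconds (timed tasks; `NA` for oddball).
#' @slot nTrials Number of stimuli (oddball tasks; `NA` otherwise).
#' @slot pOddball Per-trial oddball probability in \[0, 1\].
#' @slot isiS Inter-stimulus (onset-to-onset) interval, seconds.
#' @slot stimDurationS Stimulus display duration, seconds.
#' @seealso [taskSpec()], [sessionConfig()]
#' @export
setClass("TaskSpec",
  representation(
    kind = "character",
    durationS = "numeric",
    nTrials = "integer",
    pOddball = "numeric",
    isiS = "numeric",
    stimDurationS = "numeric"
  )
)

.taskKinds <- c("rest_eyes_open", "rest_eyes_closed", "free_recording",
                "oddball")

setValidity("TaskSpec", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !(object@kind %in% .taskKinds))
    msg <- c(msg, sprintf("task 'kind' must be one of: %s",
                          paste(.taskKinds, collapse = ", ")))
  else if (object@kind == "oddball") {
    if (is.na(object@nTrials) || object@nTrials < 1L)
      msg <- c(msg, "oddball task requires 'nTrials' >= 1")
    if (!is.na(object@durationS))
      msg <- c(msg, "oddball task must not set 'durationS' (use 'nTrials')")
    if (is.na(object@pOddball) || object@pOddball < 0 || object@pOddball > 1)
      msg <- c(msg, "'pOddball' must be in [0, 1]")
    if (is.na(object@isiS) || object@isiS <= 0)
      msg <- c(msg, "'isiS' must be positive")
  } else {
    if (is.na(object@durationS) || object@durationS <= 0)
      msg <- c(msg, sprintf("task '%s' requires positive 'durationS'",
                            object@kind))
    if (!is.na(object@nTrials))
      msg <- c(msg, "timed task must not set 'nTrials'")
  }
  if (length(msg)) msg else TRUE
})

#' Session configuration
#'
#' Ordered description of a recording session: the task sequence, the device
#' to acquire from, the map from stimulus identity to positive integer marker
#' code (0 is reserved for "no event"), and the seed that makes stimulus
#' sequences reproducible.
#'
#' @slot tasks List of [TaskSpec-class] objects, executed in order.
#' @slot device Registered device name (see [listDevices()]).
#' @slot markerMap Named integer vector mapping `standard`/`oddball` to
#'   unique positive codes.
#' @slot seed Integer seed for stimulus-sequence draws.
#' @seealso [sessionConfig()], [loadSessionConfig()], [runSession()]
#' @export
setClass("SessionConfig",
  representation(
    tasks = "list",
    device = "character",
    markerMap = "integer",
    seed = "integer"
  )
)

setValidity("SessionConfig", function(object) {
  msg <- character()
  if (!length(object@tasks))
    msg <- c(msg, "session must contain at least one task")
  if (!all(vapply(object@tasks, is, logical(1), "TaskSpec")))
    msg <- c(msg, "'tasks' must be a list of TaskSpec objects")
  mm <- object@markerMap
  if (is.null(names(mm)) || any(!nzchar(names(mm))))
    msg <- c(msg, "'markerMap' must be a named integer vector")
  if (any(mm <= 0L))
    msg <- c(msg, "marker codes must be positive (0 is reserved for no event)")
  if (anyDuplicated(mm))
    msg <- c(msg, "marker codes must be unique")
  # task boundary codes 100+i / 200+i must not collide with stimulus codes
  nT <- length(object@tasks)
  if (nT && any(mm %in% c(100L + seq_len(nT), 200L + seq_len(nT))))
    msg <- c(msg, "marker codes collide with task boundary codes (100+i/200+i)")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Simulator parameter classes
# ---------------------------------------------------------------------------

#' Background-noise specification
#'
#' Parameters of the simulated EEG background: a 1/f^a ("pink") process with
#' a target RMS amplitude, plus an optional mains-frequency sinusoid.
#'
#' @slot amplitudeUv Target RMS of the broadband background, microvolts.
#' @slot spectralExponent Exponent a of the power-law spectrum (power
#'   proportional to 1/f^a); 0 gives white noise, 1 the conventional pink
#'   EEG background.
#' @slot lineNoiseUv Peak amplitude of the mains component, microvolts.
#' @slot lineFreqHz Mains frequency, Hz (default 60).
#' @seealso [noiseSpec()], [genColoredNoise()]
#' @export
setClass("NoiseSpec",
  representation(
    amplitudeUv = "numeric",
    spectralExponent = "numeric",
    lineNoiseUv = "numeric",
    lineFreqHz = "numeric"
  )
)

setValidity("NoiseSpec", function(object) {
  msg <- character()
  if (object@amplitudeUv < 0) msg <- c(msg, "'amplitudeUv' must be >= 0")
  if (object@spectralExponent < 0)
    msg <- c(msg, "'spectralExponent' must be >= 0")
  if (object@lineNoiseUv < 0) msg <- c(msg, "'lineNoiseUv' must be >= 0")
  if (object@lineFreqHz <= 0) msg <- c(msg, "'lineFreqHz' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Oscillation specification
#'
#' A narrowband rhythm whose amplitude depends on the behavioral state
#' (eyes open / eyes closed). The default simulator uses one of these for
#' the posterior alpha rhythm, with the eyes-closed gain producing the
#' classic alpha-blocking contrast.
#'
#' @slot centerFreqHz Oscillation frequency, Hz.
#' @slot amplitudeUv Baseline peak amplitude, microvolts.
#' @slot stateGain Named nonnegative multipliers per behavioral state,
#'   e.g. `c(eyes_open = 1, eyes_closed = 2)`; states missing from the map
#'   get gain 1.
#' @seealso [oscillationSpec()], [addOscillation()]
#' @export
setClass("OscillationSpec",
  representation(
    centerFreqHz = "numeric",
    amplitudeUv = "numeric",
    stateGain = "numeric"
  )
)

setValidity("OscillationSpec", function(object) {
  msg <- character()
  if (object@centerFreqHz <= 0) msg <- c(msg, "'centerFreqHz' must be > 0")
  if (object@amplitudeUv < 0) msg <- c(msg, "'amplitudeUv' must be >= 0")
  if (any(object@stateGain < 0)) msg <- c(msg, "state gains must be >= 0")
  if (length(object@stateGain) && is.null(names(object@stateGain)))
    msg <- c(msg, "'stateGain' must be named by behavioral state")
  if (length(msg)) msg else TRUE
})

#' Event-related potential template
#'
#' Deterministic stimulus-locked waveform injected by the simulator: a sum
#' of Gaussian bumps, one per ERP component. Each component peaks at its
#' latency with peak value `amplitudeUv * channelGain`, signed by polarity;
#' the Gaussian standard deviation is the component width.
#'
#' @slot components data.frame with columns `latencyS`, `widthS`,
#'   `amplitudeUv`, `polarity` (`"+"` or `"-"`), one row per component.
#' @slot channelGains Named per-channel multipliers.
#' @seealso [erpTemplate()], [renderErp()]
#' @export
setClass("ErpTemplate",
  representation(components = "data.frame", channelGains = "numeric")
)

setValidity("ErpTemplate", function(object) {
  msg <- character()
  need <- c("latencyS", "widthS", "amplitudeUv", "polarity")
  if (!all(need %in% names(object@components)))
    msg <- c(msg, sprintf("'components' must have columns: %s",
                          paste(need, collapse = ", ")))
  else if (nrow(object@components)) {
    if (any(object@components$widthS <= 0))
      msg <- c(msg, "component widths must be > 0")
    if (any(object@components$amplitudeUv < 0))
      msg <- c(msg, "component amplitudes must be >= 0 (sign via 'polarity')")
    if (!all(object@components$polarity %in% c("+", "-")))
      msg <- c(msg, "polarity must be '+' or '-'")
  }
  if (length(object@channelGains) && is.null(names(object@channelGains)))
    msg <- c(msg, "'channelGains' must be named by channel")
  if (length(msg)) msg else TRUE
})

#' Simulation plan
#'
#' Complete, reproducible description of one simulated wearable-EEG session:
#' the session configuration (task sequence and markers), background-noise
#' and oscillation parameters, the ERP templates injected at oddball and
#' standard stimulus onsets, and the master seed. Identical plans produce
#' bitwise-identical recordings.
#'
#' @slot session A [SessionConfig-class].
#' @slot noise A [NoiseSpec-class].
#' @slot oscillations List of [OscillationSpec-class] objects.
#' @slot oddballTemplate ERP template added at oddball stimulus onsets.
#' @slot standardTemplate ERP template added at standard onsets (may have
#'   zero components).
#' @slot seed Master integer seed.
#' @slot maxDurationS Refusal threshold for runaway sessions, seconds.
#' @seealso [simulationPlan()], [simulateRecording()]
#' @export
setClass("SimulationPlan",
  representation(
    session = "SessionConfig",
    noise = "NoiseSpec",
    oscillations = "list",
    oddballTemplate = "ErpTemplate",
    standardTemplate = "ErpTemplate",
    seed = "integer",
    maxDurationS = "numeric"
  )
)

setValidity("SimulationPlan", function(object) {
  msg <- character()
  if (!all(vapply(object@oscillations, is, logical(1), "OscillationSpec")))
    msg <- c(msg, "'oscillations' must be a list of OscillationSpec objects")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (object@maxDurationS <= 0) msg <- c(msg, "'maxDurationS' must be > 0")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Recording
# ---------------------------------------------------------------------------

#' Timestamped multichannel EEG recording
#'
#' The central data container: a channels x n voltage matrix (microvolts)
#' with strictly increasing per-sample timestamps (seconds from session
#' start), an integer marker channel (0 = no event, positive codes mark
#' stimulus and task-boundary events), the device specification, the session
#' configuration the recording was acquired under (or NULL), and free-form
#' metadata. Serialized to/from the zipped-CSV artifact by
#' [writeRecording()] / [readRecording()].
#'
#' @slot timestamps Seconds, strictly increasing, uniform spacing 1/fs.
#' @slot data Channels x n matrix, microvolts; rownames are channel labels.
#' @slot marker Length-n nonnegative integer vector.
#' @slot device A [DeviceSpec-class].
#' @slot session A [SessionConfig-class] or NULL.
#' @slot metadata Free-form named list.
#' @export
setClass("EEGRecording",
  representation(
    timestamps = "numeric",
    data = "matrix",
    marker = "integer",
    device = "DeviceSpec",
    session = "ANY",
    metadata = "list"
  ),
  prototype(session = NULL, metadata = list())
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  n <- length(object@timestamps)
  if (ncol(object@data) != n)
    msg <- c(msg, "data must have one column per timestamp")
  if (length(object@marker) != n)
    msg <- c(msg, "marker must have one entry per timestamp")
  if (any(object@marker < 0L))
    msg <- c(msg, "marker codes must be nonnegative")
  if (n > 1L && any(diff(object@timestamps) <= 0))
    msg <- c(msg, "timestamps must be strictly increasing")
  if (is.null(rownames(object@data)))
    msg <- c(msg, "data must have channel rownames")
  if (!is.null(object@session) && !is(object@session, "SessionConfig"))
    msg <- c(msg, "'session' must be a SessionConfig or NULL")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Epochs and analysis results
# ---------------------------------------------------------------------------

#' Set of fixed-length epochs
#'
#' Epochs x channels x time array of signal windows sharing a common time
#' axis, with one condition label per epoch. Produced by [segmentRest()]
#' (time-locked rest windows) and [extractErpEpochs()] (stimulus-locked ERP
#' windows).
#'
#' @slot epochs Numeric array, epochs x channels x time (microvolts).
#' @slot times Time axis in seconds (relative to stimulus onset for ERP
#'   epochs; relative to window start for rest epochs).
#' @slot labels Condition label per epoch (e.g. `"oddball"`/`"standard"`,
#'   `"eyes_open"`/`"eyes_closed"`).
#' @slot fs Sampling rate, Hz.
#' @slot channelNames Channel labels, matching dim 2.
#' @slot metadata Free-form list (e.g. count of edge-dropped epochs).
#' @export
setClass("EpochSet",
  representation(
    epochs = "array",
    times = "numeric",
    labels = "character",
    fs = "numeric",
    channelNames = "character",
    metadata = "list"
  ),
  prototype(metadata = list())
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3L)
    msg <- c(msg, "'epochs' must be a 3-d array (epochs x channels x time)")
  else {
    if (d[1L] != length(object@labels))
      msg <- c(msg, "one label per epoch required")
    if (d[2L] != length(object@channelNames))
      msg <- c(msg, "one channel name per channel required")
    if (d[3L] != length(object@times))
      msg <- c(msg, "'times' must match the time dimension")
  }
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Cluster-based permutation test result
#'
#' Per-channel result of the cluster-based permutation t-test comparing two
#' epoch conditions: the suprathreshold clusters (time interval, mass =
#' summed |t|, permutation p-value), the observed t-trace, and the
#' parameters used. The smallest attainable p is
#' 1 / (nPermutations + 1).
#'
#' @slot clusters data.frame with columns `startS`, `endS`, `mass`, `p`,
#'   ordered, non-overlapping.
#' @slot channel Channel the test was run on.
#' @slot tObserved Observed t statistic per time sample.
#' @slot times Time axis, seconds.
#' @slot params List: `clusterFormingP`, `nPermutations`, `seed`,
#'   `tThreshold`, condition labels and group sizes.
#' @seealso [clusterPermutationTest()]
#' @export
setClass("ClusterTestResult",
  representation(
    clusters = "data.frame",
    channel = "character",
    tObserved = "numeric",
    times = "numeric",
    params = "list"
  )
)

setValidity("ClusterTestResult", function(object) {
  msg <- character()
  cl <- object@clusters
  need <- c("startS", "endS", "mass", "p")
  if (!all(need %in% names(cl)))
    msg <- c(msg, sprintf("'clusters' must have columns: %s",
                          paste(need, collapse = ", ")))
  else if (nrow(cl)) {
    if (any(cl$p <= 0 | cl$p > 1)) msg <- c(msg, "cluster p must be in (0, 1]")
    if (nrow(cl) > 1L && any(cl$startS[-1L] <= cl$endS[-nrow(cl)]))
      msg <- c(msg, "clusters must be ordered and non-overlapping")
  }
  if (length(object@tObserved) != length(object@times))
    msg <- c(msg, "'tObserved' must match 'times'")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# MDM classifier
# ---------------------------------------------------------------------------

#' Minimum-distance-to-means model
#'
#' Fitted single-epoch classifier: per-class mean covariance matrices
#' (geometric Karcher means under the affine-invariant Riemannian metric, or
#' arithmetic means under the Euclidean ablation), together with the ERP
#' prototype waveform used to build super-trial covariances at prediction
#' time.
#'
#' @slot classes Class labels, lexicographically sorted.
#' @slot means List of per-class mean SPD matrices (same order as `classes`).
#' @slot prototype Channels x time ERP prototype (mean training oddball
#'   epoch) stacked over each epoch before covariance estimation.
#' @slot metric `"riemannian"` or `"euclidean"`.
#' @slot shrinkage Shrinkage weight used for covariance regularization.
#' @slot channelNames Channel labels of the training epochs.
#' @seealso [fitMdm()], [predictMdm()], [evaluateCv()]
#' @export
setClass("MdmModel",
  representation(
    classes = "character",
    means = "list",
    prototype = "matrix",
    metric = "character",
    shrinkage = "numeric",
    channelNames = "character"
  )
)

setValidity("MdmModel", function(object) {
  msg <- character()
  if (length(object@classes) != length(object@means))
    msg <- c(msg, "one mean matrix per class required")
  dims <- vapply(object@means, nrow, integer(1))
  if (length(dims) && length(unique(dims)) != 1L)
    msg <- c(msg, "class means must share one dimension")
  if (!object@metric %in% c("riemannian", "euclidean"))
    msg <- c(msg, "'metric' must be 'riemannian' or 'euclidean'")
  if (length(msg)) msg else TRUE
})

#' Cross-validated classifier report
#'
#' Pooled out-of-fold performance of the minimum-distance-to-means
#' classifier: accuracy, rank-based AUC, the 2x2 confusion matrix, and the
#' Pearson chi-square test (no continuity correction) of association between
#' true and predicted labels.
#'
#' @slot accuracy Fraction of correctly labeled epochs, in \[0, 1\].
#' @slot auc Area under the ROC curve of the distance-difference score.
#' @slot confusion 2x2 count matrix, rows = truth, columns = predicted.
#' @slot chisq Pearson chi-square statistic of the confusion table.
#' @slot pValue Chi-square p-value.
#' @slot folds Number of cross-validation folds.
#' @slot seed Seed used to draw the stratified folds.
#' @seealso [evaluateCv()]
#' @export
setClass("ClassifierReport",
  representation(
    accuracy = "numeric",
    auc = "numeric",
    confusion = "matrix",
    chisq = "numeric",
    pValue = "numeric",
    folds = "integer",
    seed = "integer"
  )
)

setValidity("ClassifierReport", function(object) {
  msg <- character()
  if (object@accuracy < 0 || object@accuracy > 1)
    msg <- c(msg, "'accuracy' must be in [0, 1]")
  if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1))
    msg <- c(msg, "'auc' must be in [0, 1]")
  if (!all(dim(object@confusion) == c(2L, 2L)))
    msg <- c(msg, "'confusion' must be 2x2")
  tot <- sum(object@confusion)
  if (tot > 0 &&
      abs(object@accuracy - sum(diag(object@confusion)) / tot) > 1e-12)
    msg <- c(msg, "'accuracy' must equal trace(confusion)/sum(confusion)")
  if (length(msg)) msg else TRUE
})
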