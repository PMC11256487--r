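# Device abstraction: the registry of supported wearables, the replay
# streaming backend, and the pre-session electrode signal-quality gate.

.deviceRegistry <- new.env(parent = emptyenv())

.populateRegistry <- function() {
  registerDevice(new("DeviceSpec", name = "muse2",
                     channelNames = c("TP9", "AF7", "AF8", "TP10"),
                     samplingRate = 256, reference = "Fpz",
                     provisional = FALSE))
  registerDevice(new("DeviceSpec", name = "muses",
                     channelNames = c("TP9", "AF7", "AF8", "TP10"),
                     samplingRate = 256, reference = "Fpz",
                     provisional = FALSE))
  # 14-channel saline montage; vendor documentation of the exact layout is
  # incomplete, so the entry is flagged provisional.
  registerDevice(new("DeviceSpec", name = "epocx",
                     channelNames = c("AF3", "F7", "F3", "FC5", "T7", "P7",
                                      "O1", "O2", "P8", "T8", "FC6", "F4",
                                      "F8", "AF4"),
                     samplingRate = 128, reference = "CMS",
                     provisional = TRUE))
  # mirrors the simulator defaults
  registerDevice(new("DeviceSpec", name = "virtual",
                     channelNames = c("TP9", "AF7", "AF8", "TP10"),
                     samplingRate = 256, reference = "Fpz",
                     provisional = FALSE))
}

#' Register a device specification
#'
#' Extends the registry of supported wearables ("hard-coded but
#' modifiable"): subsequent [getDeviceSpec()] calls resolve the new name.
#'
#' @param spec A [DeviceSpec-class].
#' @return `spec`, invisibly.
#' @export
registerDevice <- function(spec) {
  validObject(spec)
  assign(spec@name, spec, envir = .deviceRegistry)
  invisible(spec)
}

#' List registered device names
#'
#' @return Character vector of registry identifiers.
#' @export
listDevices <- function() sort(ls(.deviceRegistry))

#' Look up a device specification
#'
#' @param name Registry identifier, e.g. `"muse2"` or `"virtual"`.
#' @return The immutable [DeviceSpec-class]; unknown names raise a lookup
#'   error listing the registered devices.
#' @examples
#' getDeviceSpec("muse2")
#' @export
getDeviceSpec <- function(name) {
  if (!exists(name, envir = .deviceRegistry, inherits = FALSE))
    stop(sprintf("unknown device '%s' (registered devices: %s)", name,
                 paste(listDevices(), collapse = ", ")), call. = FALSE)
  get(name, envir = .deviceRegistry, inherits = FALSE)
}

#' Construct a stream chunk
#'
#' @param timestamps Strictly increasing sample times, seconds.
#' @param samples Channels x n voltage matrix (microvolts), rownames =
#'   channel labels.
#' @return A [StreamChunk-class].
#' @export
streamChunk <- function(timestamps, samples) {
  new("StreamChunk", timestamps = as.numeric(timestamps),
      samples = samples)
}

#' Replay a recording as a live chunk stream
#'
#' The replay backend that makes a stored recording behave like a device:
#' the recording is cut into consecutive chunks of `chunkSize` samples
#' (last chunk possibly shorter). Concatenating the chunks reproduces the
#' recording exactly, in order.
#'
#' @param recording An [EEGRecording-class].
#' @param chunkSize Samples per chunk (>= 1).
#' @return List of [StreamChunk-class] objects.
#' @examples
#' rec <- simulateRecording(simulationPlan(
#'   sessionConfig(list(taskSpec("rest_eyes_open", durationS = 2)))))
#' length(streamRecording(rec, 100))
#' @export
streamRecording <- function(recording, chunkSize) {
  validObject(recording)
  stopIf(chunkSize < 1L, "'chunkSize' must be >= 1")
  chunkSize <- as.integer(chunkSize)
  n <- nSamples(recording)
  starts <- seq(1L, n, by = chunkSize)
  lapply(starts, function(s) {
    idx <- s:min(s + chunkSize - 1L, n)
    streamChunk(recording@timestamps[idx],
                recording@data[, idx, drop = FALSE])
  })
}

#' Concatenate a chunk stream back into matrices
#'
#' @param chunks List of [StreamChunk-class] objects in stream order.
#' @return List with `timestamps` and `samples` (channels x n).
#' @export
concatenateChunks <- function(chunks) {
  list(timestamps = do.call(c, lapply(chunks, function(ch) ch@timestamps)),
       samples = do.call(cbind, lapply(chunks, function(ch) ch@samples)))
}

#' Assess electrode signal quality
#'
#' The pre-session gate: per-electrode signal variability is measured as
#' the standard deviation over the most recent second of the supplied
#' window, and classified against two thresholds — `accepted` when
#' sd <= `acceptUv`, `rejected` when sd >= `rejectUv`, `near` in between.
#' The state is monotone in the variability, and the session may start only
#' when every electrode is accepted.
#'
#' @param window A [StreamChunk-class] spanning at least
#'   `assessDurationS` seconds.
#' @param acceptUv Accept threshold, microvolts (default 20).
#' @param rejectUv Reject threshold, microvolts (default 40); must exceed
#'   `acceptUv`.
#' @param assessDurationS Assessment window, seconds (default 1).
#' @return A [QualityStatus-class].
#' @examples
#' ch <- streamChunk((0:511)/256,
#'                   matrix(rnorm(1024, sd = 5), 2, 512,
#'                          dimnames = list(c("TP9", "TP10"), NULL)))
#' assessQuality(ch)
#' @export
assessQuality <- function(window, acceptUv = 20, rejectUv = 40,
                          assessDurationS = 1) {
  validObject(window)
  stopIf(acceptUv >= rejectUv, "'acceptUv' must be below 'rejectUv'")
  ts <- window@timestamps
  span <- ts[length(ts)] - ts[1L]
  fs <- if (length(ts) > 1L) 1 / stats::median(diff(ts)) else 1
  stopIf(span + 1 / fs < assessDurationS - 1e-9,
         "window spans %.3f s, need >= %g s for quality assessment",
         span + 1 / fs, assessDurationS)
  keep <- ts > ts[length(ts)] - assessDurationS + 1e-12
  sdv <- apply(window@samples[, keep, drop = FALSE], 1L, stats::sd)
  state <- ifelse(sdv <= acceptUv, "accepted",
                  ifelse(sdv >= rejectUv, "rejected", "near"))
  names(state) <- names(sdv) <- rownames(window@samples)
  new("QualityStatus", variability = sdv, state = state,
      allAccepted = all(state == "accepted"),
      acceptThreshold = acceptUv, rejectThreshold = rejectUv)
}
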