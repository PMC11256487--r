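# Accessor generics shared across containers.

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' @rdname accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))

#' @rdname accessors
#' @export
setGeneric("deviceSpec", function(x) standardGeneric("deviceSpec"))

#' @rdname accessors
#' @export
setGeneric("recordingSession", function(x) standardGeneric("recordingSession"))
# note: the SessionConfig *constructor* is sessionConfig() in session-engine.R

#' @rdname accessors
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))

#' @rdname accessors
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' @rdname accessors
#' @export
setGeneric("epochArray", function(x) standardGeneric("epochArray"))

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' Accessors for remoteEEG containers
#'
#' Standard read accessors: `samplingRate()`, `channelNames()`,
#' `nSamples()`, `timestamps()`, `markers()`, `eegData()` (channels x n
#' voltage matrix), `deviceSpec()`, `recordingSession()`, and for
#' [EpochSet-class]: `epochArray()`, `epochTimes()`, `epochLabels()`,
#' `nEpochs()`.
#'
#' @param x A remoteEEG container object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("samplingRate", "DeviceSpec", function(x) x@samplingRate)

#' @rdname accessors
setMethod("channelNames", "DeviceSpec", function(x) x@channelNames)

#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(x) {
  if (length(x@timestamps) > 1L) 1 / stats::median(diff(x@timestamps))
  else x@device@samplingRate
})

#' @rdname accessors
setMethod("channelNames", "EEGRecording", function(x) rownames(x@data))

#' @rdname accessors
setMethod("nSamples", "EEGRecording", function(x) length(x@timestamps))

#' @rdname accessors
setMethod("timestamps", "EEGRecording", function(x) x@timestamps)

#' @rdname accessors
setMethod("markers", "EEGRecording", function(x) x@marker)

#' @rdname accessors
setMethod("eegData", "EEGRecording", function(x) x@data)

#' @rdname accessors
setMethod("deviceSpec", "EEGRecording", function(x) x@device)

#' @rdname accessors
setMethod("recordingSession", "EEGRecording", function(x) x@session)

#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@fs)

#' @rdname accessors
setMethod("channelNames", "EpochSet", function(x) x@channelNames)

#' @rdname accessors
setMethod("epochLabels", "EpochSet", function(x) x@labels)

#' @rdname accessors
setMethod("epochTimes", "EpochSet", function(x) x@times)

#' @rdname accessors
setMethod("epochArray", "EpochSet", function(x) x@epochs)

#' @rdname accessors
setMethod("nEpochs", "EpochSet", function(x) dim(x@epochs)[1L])

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "DeviceSpec", function(object) {
  cat(sprintf("DeviceSpec '%s'%s: %d channels [%s] @ %g Hz, ref %s\n",
              object@name,
              if (object@provisional) " (provisional)" else "",
              length(object@channelNames),
              paste(object@channelNames, collapse = ", "),
              object@samplingRate, object@reference))
})

setMethod("show", "QualityStatus", function(object) {
  cat("QualityStatus (accept <=", object@acceptThreshold,
      "uV, reject >=", object@rejectThreshold, "uV)\n")
  for (ch in names(object@variability))
    cat(sprintf("  %-6s sd = %7.2f uV  %s\n", ch, object@variability[[ch]],
                object@state[[ch]]))
  cat(if (object@allAccepted) "  all electrodes accepted\n"
      else "  NOT ready: some electrodes not accepted\n")
})

setMethod("show", "SessionConfig", function(object) {
  cat(sprintf("SessionConfig: %d tasks on device '%s', seed %d\n",
              length(object@tasks), object@device, object@seed))
  for (i in seq_along(object@tasks)) {
    t <- object@tasks[[i]]
    desc <- if (t@kind == "oddball")
      sprintf("%d trials, p(oddball)=%.2f, isi %.2fs", t@nTrials,
              t@pOddball, t@isiS)
    else sprintf("%.0f s", t@durationS)
    cat(sprintf("  %d. %-16s %s\n", i, t@kind, desc))
  }
})

setMethod("show", "EEGRecording", function(object) {
  fs <- samplingRate(object)
  cat(sprintf(
    "EEGRecording: %d channels x %d samples (%.1f s @ %.6g Hz), device '%s'\n",
    nrow(object@data), nSamples(object),
    nSamples(object) / fs, fs, object@device@name))
  nm <- sum(object@marker > 0L)
  cat(sprintf("  channels: %s\n  markers: %d events\n",
              paste(rownames(object@data), collapse = ", "), nm))
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples @ %g Hz\n",
              dim(object@epochs)[1L], dim(object@epochs)[2L],
              dim(object@epochs)[3L], object@fs))
  print(table(object@labels))
})

setMethod("show", "ClusterTestResult", function(object) {
  cat(sprintf(
    "ClusterTestResult [%s]: %d cluster(s), %d permutations (min p = %.4g)\n",
    object@channel, nrow(object@clusters),
    object@params$nPermutations, 1 / (object@params$nPermutations + 1)))
  if (nrow(object@clusters)) print(object@clusters)
})

setMethod("show", "MdmModel", function(object) {
  cat(sprintf("MdmModel (%s metric): classes %s, covariance dim %d\n",
              object@metric, paste(object@classes, collapse = "/"),
              nrow(object@means[[1L]])))
})

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf(
    "ClassifierReport: accuracy %.4f, AUC %.4f (%d-fold CV, seed %d)\n",
    object@accuracy, object@auc, object@folds, object@seed))
  print(object@confusion)
  cat(sprintf("  chi-square = %.3f, p = %.4g\n", object@chisq,
              object@pValue))
})
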