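# Session engine: config parsing and validation, oddball sequence drawing,
# event scheduling, and marker placement into the timestamped stream.

#' Construct a task specification
#'
#' @param kind One of `"rest_eyes_open"`, `"rest_eyes_closed"`,
#'   `"free_recording"`, `"oddball"`.
#' @param durationS Duration in seconds (timed tasks).
#' @param nTrials Number of stimuli (oddball tasks).
#' @param pOddball Per-trial oddball probability (default 0.1).
#' @param isiS Onset-to-onset inter-stimulus interval, seconds (default 1).
#' @param stimDurationS Stimulus display duration, seconds (default 0.2).
#' @return A [TaskSpec-class].
#' @examples
#' taskSpec("rest_eyes_closed", durationS = 60)
#' taskSpec("oddball", nTrials = 200)
#' @export
taskSpec <- function(kind, durationS = NA_real_, nTrials = NA_integer_,
                     pOddball = 0.1, isiS = 1.0, stimDurationS = 0.2) {
  new("TaskSpec", kind = kind, durationS = as.numeric(durationS),
      nTrials = as.integer(nTrials), pOddball = pOddball, isiS = isiS,
      stimDurationS = stimDurationS)
}

#' Construct a session configuration
#'
#' @param tasks List of [TaskSpec-class] objects, run in order.
#' @param device Registered device name (default `"virtual"`).
#' @param markerMap Named positive integer codes for stimulus identities
#'   (default `standard = 1`, `oddball = 2`; 0 is reserved for "no event";
#'   task boundaries use `100 + i` / `200 + i`).
#' @param seed Integer seed for stimulus-sequence draws.
#' @return A [SessionConfig-class].
#' @export
sessionConfig <- function(tasks, device = "virtual",
                          markerMap = c(standard = 1L, oddball = 2L),
                          seed = 1L) {
  mm <- as.integer(markerMap)
  names(mm) <- names(markerMap)
  new("SessionConfig", tasks = tasks, device = device, markerMap = mm,
      seed = as.integer(seed))
}

#' Default session configuration
#'
#' The shipped default session design: a free recording, one minute each of
#' eyes-open and eyes-closed rest, an oddball block, a recovery rest, and a
#' second oddball block.
#'
#' @param nTrials Trials per oddball block (default 200).
#' @param device Device name (default `"virtual"`).
#' @param seed Integer seed.
#' @return A [SessionConfig-class].
#' @export
defaultSessionConfig <- function(nTrials = 200L, device = "virtual",
                                 seed = 1L) {
  sessionConfig(
    tasks = list(
      taskSpec("free_recording", durationS = 30),
      taskSpec("rest_eyes_open", durationS = 60),
      taskSpec("rest_eyes_closed", durationS = 60),
      taskSpec("oddball", nTrials = nTrials),
      taskSpec("rest_eyes_open", durationS = 30),
      taskSpec("oddball", nTrials = nTrials)
    ),
    device = device, seed = seed
  )
}

# Convert a SessionConfig to/from a plain list (YAML / JSON serialization).
sessionConfigToList <- function(config) {
  list(
    format_version = 1L,
    device = config@device,
    seed = config@seed,
    marker_map = as.list(config@markerMap),
    tasks = lapply(config@tasks, function(t) {
      out <- list(kind = t@kind)
      if (t@kind == "oddball") {
        out$n_trials <- t@nTrials
        out$p_oddball <- t@pOddball
        out$isi_s <- t@isiS
        out$stim_duration_s <- t@stimDurationS
      } else out$duration_s <- t@durationS
      out
    })
  )
}

sessionConfigFromList <- function(x, where = "session config") {
  fail <- function(fmt, ...) stop(sprintf("%s: %s", where,
                                          sprintf(fmt, ...)), call. = FALSE)
  if (is.null(x$tasks) || !length(x$tasks)) fail("field 'tasks' is missing or empty")
  tasks <- lapply(seq_along(x$tasks), function(i) {
    tl <- x$tasks[[i]]
    if (is.null(tl$kind)) fail("task %d: field 'kind' missing", i)
    if (!tl$kind %in% .taskKinds)
      fail("task %d: unknown kind '%s' (known: %s)", i, tl$kind,
           paste(.taskKinds, collapse = ", "))
    if (tl$kind == "oddball") {
      if (is.null(tl$n_trials)) fail("task %d: field 'n_trials' missing", i)
      p <- if (is.null(tl$p_oddball)) 0.1 else tl$p_oddball
      if (p < 0 || p > 1)
        fail("task %d: field 'p_oddball' = %g outside [0, 1]", i, p)
      taskSpec("oddball", nTrials = tl$n_trials, pOddball = p,
               isiS = if (is.null(tl$isi_s)) 1.0 else tl$isi_s,
               stimDurationS = if (is.null(tl$stim_duration_s)) 0.2
                               else tl$stim_duration_s)
    } else {
      if (is.null(tl$duration_s))
        fail("task %d: field 'duration_s' missing", i)
      taskSpec(tl$kind, durationS = tl$duration_s)
    }
  })
  mm <- x$marker_map
  if (is.null(mm)) mm <- list(standard = 1L, oddball = 2L)
  codes <- vapply(mm, function(v) as.integer(v), integer(1))
  if (any(codes <= 0L))
    fail("field 'marker_map' contains non-positive code (0 is reserved)")
  if (anyDuplicated(codes)) fail("field 'marker_map' contains duplicate codes")
  cfg <- try(sessionConfig(tasks = tasks,
                           device = if (is.null(x$device)) "virtual"
                                    else x$device,
                           markerMap = codes,
                           seed = if (is.null(x$seed)) 1L else x$seed),
             silent = TRUE)
  if (inherits(cfg, "try-error"))
    fail("%s", conditionMessage(attr(cfg, "condition")))
  cfg
}

#' Load and validate a session configuration file
#'
#' Reads the YAML session dialect (`device`, `seed`, `marker_map`, ordered
#' `tasks` each with a `kind` and its parameters) and validates every
#' invariant eagerly: known task kinds, probabilities in \[0, 1\], unique
#' positive marker codes. Validation failures name the offending field.
#'
#' @param path Path to a YAML session configuration.
#' @return A validated [SessionConfig-class].
#' @seealso [writeSessionConfig()]; a shipped example lives at
#'   `system.file("extdata", "default_session.yaml", package = "remoteEEG")`.
#' @export
loadSessionConfig <- function(path) {
  stopIf(!file.exists(path), "session config '%s' does not exist", path)
  x <- yaml::read_yaml(path)
  sessionConfigFromList(x, where = sprintf("session config '%s'", path))
}

#' Write a session configuration file
#'
#' @param config A [SessionConfig-class].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
writeSessionConfig <- function(config, path) {
  validObject(config)
  yaml::write_yaml(sessionConfigToList(config), path)
  invisible(path)
}

#' Draw an oddball stimulus sequence
#'
#' Each trial is independently an oddball with probability `pOddball`; runs
#' of consecutive oddballs longer than `maxConsecutive` are then repaired by
#' re-drawing the violating trials with the same generator, keeping the
#' sequence deterministic given the seed. (If the cap is unattainable the
#' repair falls back to forcing the excess trials to standard.)
#'
#' @param nTrials Number of trials (>= 1).
#' @param pOddball Oddball probability (default 0.1).
#' @param seed Integer seed.
#' @param maxConsecutive Cap on consecutive oddballs (default 2); `Inf`
#'   disables the repair.
#' @return Character vector of `"standard"`/`"oddball"`, length `nTrials`.
#' @examples
#' table(buildOddballSequence(200, 0.1, seed = 3))
#' @export
buildOddballSequence <- function(nTrials, pOddball = 0.1, seed = 1L,
                                 maxConsecutive = 2L) {
  stopIf(nTrials < 1L, "'nTrials' must be >= 1")
  stopIf(pOddball < 0 || pOddball > 1, "'pOddball' must be in [0, 1]")
  withSeed(seed, {
    odd <- stats::runif(nTrials) < pOddball
    if (is.finite(maxConsecutive) && pOddball < 1) {
      violating <- function(v) {
        r <- rle(v)
        bad <- which(r$values & r$lengths > maxConsecutive)
        unlist(lapply(bad, function(b) {
          s <- sum(r$lengths[seq_len(b - 1L)]) + 1L
          (s + maxConsecutive):(s + r$lengths[b] - 1L)
        }))
      }
      for (iter in seq_len(10000L)) {
        idx <- violating(odd)
        if (!length(idx)) break
        odd[idx] <- stats::runif(length(idx)) < pOddball
      }
      idx <- violating(odd)
      if (length(idx)) odd[idx] <- FALSE
    }
    ifelse(odd, "oddball", "standard")
  })
}

#' Schedule the events of a session
#'
#' Expands a session configuration into its deterministic event schedule:
#' task boundaries (codes `100 + i` at task start, `200 + i` one sample
#' before task end), stimulus onsets for every oddball block (first
#' stimulus one ISI after block start, then one per ISI), and the
#' behavioral state timeline (eyes open / eyes closed) implied by the task
#' kinds. Oddball identities are drawn with [buildOddballSequence()] seeded
#' from the config seed and the task index.
#'
#' @param config A [SessionConfig-class].
#' @return List with `events` (data.frame `onsetS`, `identity`, `code`,
#'   `task`), `stateTimeline` (data.frame `startS`, `endS`, `state`) and
#'   `durationS`.
#' @export
scheduleSession <- function(config) {
  validObject(config)
  dev <- getDeviceSpec(config@device)
  fs <- dev@samplingRate
  mm <- config@markerMap
  t0 <- 0
  ev <- list()
  tl <- list()
  for (i in seq_along(config@tasks)) {
    task <- config@tasks[[i]]
    dur <- if (task@kind == "oddball") (task@nTrials + 1L) * task@isiS
           else task@durationS
    state <- switch(task@kind, rest_eyes_closed = "eyes_closed", "eyes_open")
    ev[[length(ev) + 1L]] <- data.frame(
      onsetS = t0, identity = "task_start", code = 100L + i, task = i)
    if (task@kind == "oddball") {
      ids <- buildOddballSequence(task@nTrials, task@pOddball,
                                  seed = deriveSeed(config@seed, i))
      ev[[length(ev) + 1L]] <- data.frame(
        onsetS = t0 + seq_len(task@nTrials) * task@isiS,
        identity = ids, code = mm[ids], task = i)
    }
    ev[[length(ev) + 1L]] <- data.frame(
      onsetS = t0 + dur - 1 / fs, identity = "task_end", code = 200L + i,
      task = i)
    tl[[length(tl) + 1L]] <- data.frame(startS = t0, endS = t0 + dur,
                                        state = state)
    t0 <- t0 + dur
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$onsetS), ]
  rownames(events) <- NULL
  list(events = events, stateTimeline = do.call(rbind, tl), durationS = t0)
}

# Place event codes on the sample grid: each event goes to the sample whose
# timestamp is nearest its onset; if that sample is taken, the later event
# moves forward to the next free sample (no marker is ever lost).
placeMarkers <- function(events, ts) {
  n <- length(ts)
  fs <- 1 / stats::median(diff(ts))
  marker <- integer(n)
  for (i in seq_len(nrow(events))) {
    j <- round((events$onsetS[i] - ts[1L]) * fs) + 1L
    j <- max(1L, min(n, j))
    while (j <= n && marker[j] != 0L) j <- j + 1L
    stopIf(j > n, "no free sample left for event at %.3f s",
           events$onsetS[i])
    marker[j] <- as.integer(events$code[i])
  }
  marker
}

#' Run a session against a chunk stream
#'
#' Consumes the ordered stream of [StreamChunk-class] objects an acquisition
#' backend produces, concatenates the samples, and merges the session's
#' scheduled marker codes into the timestamped stream: each event lands on
#' the sample nearest its onset, collisions shift the later event to the
#' next sample. Errors if the stream is exhausted before the session ends,
#' reporting the last completed task.
#'
#' @param config A [SessionConfig-class].
#' @param source A list of [StreamChunk-class] objects (e.g. from
#'   [streamRecording()]) or an [EEGRecording-class] to replay.
#' @return An [EEGRecording-class] with the scheduled markers merged in.
#' @examples
#' cfg <- sessionConfig(list(taskSpec("rest_eyes_open", durationS = 2)))
#' raw <- simulateRecording(simulationPlan(cfg))
#' rec <- runSession(cfg, streamRecording(raw, 256))
#' @export
runSession <- function(config, source) {
  validObject(config)
  if (is(source, "EEGRecording")) source <- streamRecording(source,
                                                            nSamples(source))
  stopIf(!length(source), "'source' delivered no chunks")
  ts <- do.call(c, lapply(source, function(ch) ch@timestamps))
  dat <- do.call(cbind, lapply(source, function(ch) ch@samples))
  stopIf(any(diff(ts) <= 0), "chunk timestamps are not strictly increasing")
  sched <- scheduleSession(config)
  fs <- getDeviceSpec(config@device)@samplingRate
  have <- ts[length(ts)] - ts[1L] + 1 / fs
  if (have + 0.5 / fs < sched$durationS) {
    done <- which(vapply(seq_along(config@tasks), function(i) {
      endI <- max(sched$events$onsetS[sched$events$task == i])
      endI <= ts[length(ts)] - ts[1L] + 0.5 / fs
    }, logical(1)))
    stop(sprintf(
      "stream exhausted after %.2f s of a %.2f s session (last completed task: %s)",
      have, sched$durationS,
      if (length(done)) sprintf("%d of %d", max(done),
                                length(config@tasks)) else "none"),
      call. = FALSE)
  }
  marker <- placeMarkers(sched$events, ts - ts[1L])
  new("EEGRecording", timestamps = ts - ts[1L], data = dat, marker = marker,
      device = getDeviceSpec(config@device), session = config,
      metadata = list(source = "stream"))
}

#' Describe a stimulus for a renderer
#'
#' The engine never draws; it emits display descriptors a renderer can
#' consume. Standards are green circles, oddballs blue circles; task
#' boundary events have no visual.
#'
#' @param identity One of `"standard"`, `"oddball"`, `"task_start"`,
#'   `"task_end"`.
#' @return A named list, e.g. `list(shape = "circle", color = "green")`;
#'   empty for boundary events.
#' @export
describeStimulus <- function(identity) {
  switch(identity,
    standard = list(shape = "circle", color = "green"),
    oddball = list(shape = "circle", color = "blue"),
    task_start = ,
    task_end = list(),
    stop(sprintf(
      "unknown stimulus identity '%s' (known: standard, oddball, task_start, task_end)",
      identity), call. = FALSE)
  )
}
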