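# Shared fixture builders: all data are generated in code at test time.

# A minimal rest-only session of the given length.
restConfig <- function(closedS = 10, openS = 10, seed = 1L) {
  sessionConfig(list(taskSpec("rest_eyes_closed", durationS = closedS),
                     taskSpec("rest_eyes_open", durationS = openS)),
                seed = seed)
}

# A single-block oddball session.
oddballConfig <- function(nTrials = 40L, pOddball = 0.1, seed = 1L) {
  sessionConfig(list(taskSpec("oddball", nTrials = nTrials,
                              pOddball = pOddball)),
                seed = seed)
}

# Small synthetic EpochSet built directly from a generator function
# f(epochIndex) -> channels x time matrix.
makeEpochSet <- function(n, labels, f, fs = 256,
                         channels = c("TP9", "TP10")) {
  proto <- f(1L)
  arr <- array(0, dim = c(n, nrow(proto), ncol(proto)))
  for (e in seq_len(n)) arr[e, , ] <- f(e)
  new("EpochSet", epochs = arr,
      times = (seq_len(ncol(proto)) - 1L) / fs,
      labels = labels, fs = fs, channelNames = channels)
}

randomSpd <- function(d, seed) {
  set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  crossprod(A) + diag(d)
}
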