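# ERP analysis: stimulus-locked epoching with baseline correction,
# condition averaging, and the cluster-based permutation t-test.

#' Extract stimulus-locked ERP epochs
#'
#' One epoch per stimulus marker whose window lies fully inside the
#' recording (edge-crossing epochs are dropped and counted). The epoch
#' spans `tmin`..`tmax` seconds around the marker sample
#' (`round((tmax - tmin) * fs) + 1` samples) and the per-channel mean over
#' the baseline window is subtracted from each epoch.
#'
#' @param recording A (typically bandpassed) [EEGRecording-class] with
#'   markers.
#' @param markerMap Named codes to epoch, identity -> code (default: the
#'   recording session's stimulus map, or `c(standard = 1, oddball = 2)`).
#' @param tmin,tmax Epoch window relative to stimulus onset, seconds
#'   (defaults -0.2 and 0.8).
#' @param baseline Length-2 baseline window, seconds (default
#'   `c(-0.2, 0)`); NULL disables baseline correction.
#' @return An [EpochSet-class] labeled by stimulus identity;
#'   `metadata$dropped` counts edge-dropped epochs. Empty (with a warning)
#'   when no requested marker is present.
#' @export
extractErpEpochs <- function(recording, markerMap = NULL, tmin = -0.2,
                             tmax = 0.8, baseline = c(-0.2, 0)) {
  validObject(recording)
  stopIf(tmin >= tmax, "'tmin' must be below 'tmax'")
  if (is.null(markerMap)) {
    cfg <- recordingSession(recording)
    markerMap <- if (!is.null(cfg)) cfg@markerMap
                 else c(standard = 1L, oddball = 2L)
  }
  fs <- samplingRate(recording)
  n <- nSamples(recording)
  chans <- channelNames(recording)
  iRel <- round(tmin * fs):round(tmax * fs)
  times <- iRel / fs
  onsets <- which(recording@marker %in% markerMap)
  if (!length(onsets)) {
    warning("no markers with the requested codes; returning empty EpochSet")
    return(new("EpochSet",
               epochs = array(0, dim = c(0L, length(chans), length(iRel))),
               times = times, labels = character(), fs = fs,
               channelNames = chans, metadata = list(dropped = 0L)))
  }
  inside <- onsets + min(iRel) >= 1L & onsets + max(iRel) <= n
  dropped <- sum(!inside)
  if (dropped)
    message(sprintf("dropped %d epoch(s) crossing the recording edges",
                    dropped))
  onsets <- onsets[inside]
  idName <- names(markerMap)[match(recording@marker[onsets], markerMap)]
  arr <- array(0, dim = c(length(onsets), length(chans), length(iRel)))
  for (e in seq_along(onsets)) {
    seg <- recording@data[, onsets[e] + iRel, drop = FALSE]
    if (!is.null(baseline)) {
      bl <- times >= baseline[1L] - 1e-12 & times <= baseline[2L] + 1e-12
      seg <- seg - rowMeans(seg[, bl, drop = FALSE])
    }
    arr[e, , ] <- seg
  }
  new("EpochSet", epochs = arr, times = times, labels = idName, fs = fs,
      channelNames = chans, metadata = list(dropped = dropped))
}

#' Average ERP per condition
#'
#' Pointwise mean and standard error of the mean, per condition and
#' channel.
#'
#' @param epochs An [EpochSet-class].
#' @return Named list (one entry per condition) of lists with `mean` and
#'   `se` (channels x time matrices, `se` all-NA for single-epoch
#'   conditions) and `n`. Conditions with zero epochs are excluded with a
#'   warning.
#' @export
averageErp <- function(epochs) {
  validObject(epochs)
  stopIf(nEpochs(epochs) < 1L, "need at least one epoch")
  conds <- unique(epochs@labels)
  out <- list()
  for (cond in conds) {
    idx <- which(epochs@labels == cond)
    sub <- epochs@epochs[idx, , , drop = FALSE]
    m <- apply(sub, c(2L, 3L), mean)
    se <- if (length(idx) > 1L)
      apply(sub, c(2L, 3L), stats::sd) / sqrt(length(idx))
    else {
      warning(sprintf(
        "condition '%s' has a single epoch; standard error undefined", cond))
      matrix(NA_real_, nrow = dim(sub)[2L], ncol = dim(sub)[3L])
    }
    dimnames(m) <- dimnames(se) <- list(epochs@channelNames, NULL)
    out[[cond]] <- list(mean = m, se = se, n = length(idx))
  }
  attr(out, "times") <- epochs@times
  out
}

# Pooled-variance two-sample t statistic per time sample, vectorized over
# columns of X (epochs x time), for an arbitrary set of group-1 index
# vectors given as a 0/1 membership matrix G (epochs x draws).
.tMatrix <- function(X, G) {
  n <- nrow(X)
  n1 <- colSums(G)
  n2 <- n - n1
  s1 <- crossprod(G, X)              # draws x time: group-1 sums
  q1 <- crossprod(G, X^2)
  sAll <- matrix(colSums(X), nrow = nrow(s1), ncol = ncol(X), byrow = TRUE)
  qAll <- matrix(colSums(X^2), nrow = nrow(s1), ncol = ncol(X),
                 byrow = TRUE)
  m1 <- s1 / n1
  m2 <- (sAll - s1) / n2
  ss <- (q1 - n1 * m1^2) + ((qAll - q1) - n2 * m2^2)
  sp2 <- ss / (n - 2)
  denom <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / denom
  t[denom == 0] <- 0
  t
}

# Contiguous suprathreshold clusters of a t-trace: list of (start, end,
# mass) with mass = sum of |t| over the run.
.findClusters <- function(tvec, thr) {
  supra <- abs(tvec) > thr
  if (!any(supra)) return(data.frame(start = integer(), end = integer(),
                                     mass = numeric()))
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(keep, function(k)
               sum(abs(tvec[starts[k]:ends[k]])), numeric(1)))
}

#' Cluster-based permutation t-test on one channel
#'
#' Standard max-statistic construction: (1) a pooled-variance two-sample t
#' statistic at every time sample; (2) contiguous runs where |t| exceeds
#' the two-sided threshold at `clusterFormingP` form clusters with mass =
#' summed |t|; (3) condition labels are permuted `nPermutations` times and
#' the maximal cluster mass of each permutation forms the null
#' distribution; (4) each observed cluster gets
#' p = (1 + #\{null >= mass\}) / (nPermutations + 1), so the smallest
#' attainable p is 1/(nPermutations + 1).
#'
#' @param epochs An [EpochSet-class] with exactly two condition labels and
#'   at least 2 epochs per condition.
#' @param channel Channel to test (default first).
#' @param clusterFormingP Two-sided per-sample threshold probability
#'   (default 0.05).
#' @param nPermutations Number of label permutations (default 1000).
#' @param seed Seed for the permutation draw (the observed clusters do not
#'   depend on it).
#' @return A [ClusterTestResult-class].
#' @export
clusterPermutationTest <- function(epochs, channel = channelNames(epochs)[1L],
                                   clusterFormingP = 0.05,
                                   nPermutations = 1000L, seed = 1L) {
  validObject(epochs)
  stopIf(nPermutations < 1L, "'nPermutations' must be >= 1")
  ci <- match(channel, channelNames(epochs))
  stopIf(is.na(ci), "unknown channel '%s'", channel)
  labs <- epochs@labels
  conds <- sort(unique(labs))
  stopIf(length(conds) != 2L, "need exactly two conditions, got %d",
         length(conds))
  stopIf(min(table(labs)) < 2L, "need >= 2 epochs per condition")
  X <- epochs@epochs[, ci, ]            # epochs x time
  n <- nrow(X)
  n1 <- sum(labs == conds[1L])
  thr <- stats::qt(1 - clusterFormingP / 2, df = n - 2L)

  g0 <- matrix(as.numeric(labs == conds[1L]), ncol = 1L)
  tObs <- as.numeric(.tMatrix(X, g0))
  obs <- .findClusters(tObs, thr)

  G <- withSeed(seed, {
    vapply(seq_len(nPermutations), function(i) {
      g <- numeric(n)
      g[sample.int(n, n1)] <- 1
      g
    }, numeric(n))
  })
  Tperm <- .tMatrix(X, G)               # draws x time
  nullMass <- vapply(seq_len(nPermutations), function(i) {
    cl <- .findClusters(Tperm[i, ], thr)
    if (nrow(cl)) max(cl$mass) else 0
  }, numeric(1))

  p <- vapply(obs$mass, function(m)
    (1 + sum(nullMass >= m)) / (nPermutations + 1), numeric(1))
  clusters <- data.frame(
    startS = if (nrow(obs)) epochs@times[obs$start] else numeric(),
    endS = if (nrow(obs)) epochs@times[obs$end] else numeric(),
    mass = obs$mass, p = p)
  new("ClusterTestResult", clusters = clusters, channel = channel,
      tObserved = tObs, times = epochs@times,
      params = list(clusterFormingP = clusterFormingP,
                    nPermutations = as.integer(nPermutations),
                    seed = as.integer(seed), tThreshold = thr,
                    conditions = conds,
                    groupSizes = c(n1, n - n1)))
}
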