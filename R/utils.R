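# Internal helpers: seeded evaluation, seed derivation, Welch PSD.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic stream splitting: derive a sub-seed for component `k` of a
# master seed, kept inside 32-bit integer range.
deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483629)
}

stopIf <- function(cond, fmt, ...) if (cond) stop(sprintf(fmt, ...),
                                                 call. = FALSE)

hannWindow <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0L, n - 1L) / (n - 1L))
}

# Welch power spectral density estimate.
#
# Segments of `segLength` samples with fractional `overlap`, Hann-tapered
# modified periodograms averaged across segments. Returns one-sided
# frequencies and densities; absolute scaling is one-sided
# power-per-frequency (band integrals of relative power are scale-free).
welchPsd <- function(x, fs, segLength = round(fs), overlap = 0.5) {
  n <- length(x)
  segLength <- as.integer(segLength)
  stopIf(segLength < 2L, "Welch segment length must be >= 2")
  if (segLength > n) segLength <- n
  step <- max(1L, as.integer(round(segLength * (1 - overlap))))
  starts <- seq(1L, n - segLength + 1L, by = step)
  w <- hannWindow(segLength)
  u <- sum(w^2)
  nfft <- segLength
  nfreq <- nfft %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + segLength - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / (u * fs)
    acc <- acc + p[seq_len(nfreq)]
  }
  psd <- acc / length(starts)
  # fold two-sided power into one-sided density (not DC / Nyquist)
  inner <- 2:(nfreq - if (nfft %% 2L == 0L) 1L else 0L)
  psd[inner] <- 2 * psd[inner]
  list(freq = (seq_len(nfreq) - 1L) * fs / nfft, psd = psd)
}
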