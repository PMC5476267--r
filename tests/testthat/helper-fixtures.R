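# Shared fixtures: all built in code, no stored data.

toneSignal <- function(freq, duration = 1, rate = 22050, amp = 1) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  new("AudioSignal", samples = amp * sin(2 * pi * freq * t),
      sampleRate = rate)
}

# Spectrogram object around an arbitrary non-negative matrix on the
# standard 20 ms / 10 ms analysis grid.
specFromMatrix <- function(M, rate = 22050) {
  new("Spectrogram", mag = M,
      freqs = seq(0, rate / 2, length.out = nrow(M)),
      frameShift = 0.010, windowLength = 0.020, sampleRate = rate)
}

# Burst spectrogram: flat level inside each (start, end] frame range
# (1-based inclusive), silence elsewhere; level is linear magnitude.
burstSpectrogram <- function(nFrames, bursts, nBins = 20) {
  M <- matrix(0, nBins, nFrames)
  for (b in bursts) {
    M[, b$start:b$end] <- b$level
  }
  specFromMatrix(M)
}

# All permutations of a vector (brute-force assignment oracle).
allPerms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(allPerms(v[-i]), function(r) c(v[i], r))
  }))
}

# Small labeled Gaussian-cluster feature set for classifier tests.
clusterData <- function(n = 30, d = 4, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n * d), n, d),
               matrix(rnorm(n * d, mean = sep), n, d))
    list(X = X, y = rep(c("a", "b"), each = n))
  })
}

# Tiny positive spectrogram list for dimensionality-contract tests.
tinySpecs <- function(nSpecs = 1, nBins = 30, nFrames = 40, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(nSpecs), function(i) {
      specFromMatrix(matrix(stats::rexp(nBins * nFrames), nBins, nFrames))
    })
  })
}
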