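# Audio ingestion, band-pass filtering, spectrogram and segmentation.

test_that("WAV round trip preserves a mono signal and silence reads as zeros", {
  path <- withr::local_tempfile(fileext = ".wav")
  writeAudio(new("AudioSignal", samples = rep(0, 22050), sampleRate = 22050),
             path)
  x <- readAudio(path, targetRate = 22050)
  expect_length(samples(x), 22050)
  expect_true(all(samples(x) == 0))

  tone <- toneSignal(440, duration = 0.5)
  writeAudio(tone, path)
  y <- readAudio(path, targetRate = 22050)
  expect_length(samples(y), length(samples(tone)))
  # 16-bit quantization error only
  expect_lt(max(abs(samples(y) - samples(tone))), 1 / 32000)
})

test_that("stereo files are channel-averaged to mono of the same duration", {
  path <- withr::local_tempfile(fileext = ".wav")
  n <- 8000
  left <- sin(2 * pi * 500 * (0:(n - 1)) / 22050)
  right <- -left                      # cancels on averaging
  pcm <- as.integer(round(32000 * as.vector(rbind(left, right))))
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 4 * n), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(2L, con, 2, endian = "little")      # stereo
  writeBin(22050L, con, 4, endian = "little")
  writeBin(as.integer(22050 * 4), con, 4, endian = "little")
  writeBin(4L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(4 * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  close(con)

  x <- readAudio(path, targetRate = 22050)
  expect_length(samples(x), n)
  expect_lt(max(abs(samples(x))), 1e-4)   # channels cancel
})

test_that("a 44.1 kHz tone resampled to 22.05 kHz keeps its dominant bin", {
  path <- withr::local_tempfile(fileext = ".wav")
  writeAudio(toneSignal(1000, duration = 0.5, rate = 44100), path)
  x <- readAudio(path, targetRate = 22050)
  expect_equal(sampleRate(x), 22050)
  spec <- magnitudeSpectrogram(x)
  V <- specMatrix(spec)
  dominant <- binFreqs(spec)[which.max(rowSums(V))]
  expect_lt(abs(dominant - 1000), 22050 / 512)
})

test_that("unreadable and empty audio inputs raise errors naming the problem", {
  expect_error(readAudio("/nonexistent/file.wav"), "file.wav")
  path <- withr::local_tempfile(fileext = ".wav")
  writeBin(raw(10), path)
  expect_error(readAudio(path), "RIFF")
})

test_that("band-pass attenuates stop-band tones and passes in-band tones", {
  rms <- function(x) sqrt(mean(x^2))
  lowTone <- toneSignal(500, duration = 0.5)
  out <- bandpassFilter(lowTone)
  expect_lt(rms(samples(out)), 0.05 * rms(samples(lowTone)))

  midTone <- toneSignal(5000, duration = 0.5)
  out2 <- bandpassFilter(midTone)
  expect_lt(abs(rms(samples(out2)) / rms(samples(midTone)) - 1), 0.05)

  zero <- new("AudioSignal", samples = rep(0, 4410), sampleRate = 22050)
  expect_true(all(samples(bandpassFilter(zero)) == 0))
})

test_that("band-pass filtering is linear and rejects infeasible edges", {
  x <- withr::with_seed(4, new("AudioSignal", samples = rnorm(8000),
                               sampleRate = 22050))
  a <- 3.7
  ax <- new("AudioSignal", samples = a * samples(x), sampleRate = 22050)
  expect_lt(max(abs(samples(bandpassFilter(ax)) -
                    a * samples(bandpassFilter(x)))), 1e-9)
  expect_error(bandpassFilter(x, low = 1000, high = 12000), "Nyquist")
})

test_that("spectrogram frame count, non-negativity and bin layout hold", {
  silence <- new("AudioSignal", samples = rep(0, 22050), sampleRate = 22050)
  spec <- magnitudeSpectrogram(silence)
  expect_equal(nFrames(spec), 99)                 # floor((N - 441)/220) + 1
  expect_equal(nrow(specMatrix(spec)), 257)       # nFFT/2 + 1
  expect_true(all(specMatrix(spec) == 0))

  noise <- withr::with_seed(7, new("AudioSignal", samples = rnorm(11025),
                                   sampleRate = 22050))
  V <- specMatrix(magnitudeSpectrogram(noise))
  expect_true(all(V >= 0))

  tone <- toneSignal(3000, duration = 0.4)
  spec3k <- magnitudeSpectrogram(tone)
  peaks <- apply(specMatrix(spec3k), 2, which.max)
  expect_true(all(binFreqs(spec3k)[peaks] == binFreqs(spec3k)[
    which.min(abs(binFreqs(spec3k) - 3000))]))

  short <- new("AudioSignal", samples = rep(0, 100), sampleRate = 22050)
  expect_error(magnitudeSpectrogram(short), "too short")
})

test_that("segmentation finds burst boundaries and handles degenerate input", {
  spec <- burstSpectrogram(140, list(list(start = 11, end = 40, level = 1),
                                     list(start = 91, end = 120, level = 0.8)))
  segs <- segmentSyllables(spec)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$startFrame, c(10, 90))       # 0-based inclusive
  expect_equal(segs$endFrame, c(40, 120))        # 0-based exclusive

  silent <- specFromMatrix(matrix(0, 20, 50))
  expect_equal(nrow(segmentSyllables(silent)), 0)

  # amplitude never drops 20 dB below its peak -> one segment spans all
  M <- matrix(rep(1 + 0.05 * sin(seq_len(60)), each = 5), 5, 60)
  allLoud <- specFromMatrix(M)
  segs2 <- segmentSyllables(allLoud)
  expect_equal(nrow(segs2), 1)
  expect_equal(c(segs2$startFrame, segs2$endFrame), c(0, 60))
})

test_that("segments are pairwise disjoint and sorted on random spectrograms", {
  for (case in 1:100) {
    spec <- withr::with_seed(case, {
      nT <- sample(50:150, 1)
      M <- matrix(stats::rexp(10 * nT, rate = 50), 10, nT)
      nBurst <- sample(0:4, 1)
      for (b in seq_len(nBurst)) {
        s <- sample(nT - 8, 1)
        M[, s:(s + sample(3:8, 1))] <- stats::runif(1, 0.5, 2)
      }
      specFromMatrix(M)
    })
    segs <- segmentSyllables(spec)
    if (nrow(segs) > 1) {
      expect_true(all(diff(segs$startFrame) > 0))
      expect_true(all(segs$startFrame[-1] >= segs$endFrame[-nrow(segs)]))
    }
    expect_true(all(segs$endFrame - segs$startFrame >= 3))
    expect_true(all(segs$endFrame <= nFrames(spec)))
  }
})

test_that("segment tables are written as the documented CSV contract", {
  spec <- burstSpectrogram(60, list(list(start = 6, end = 25, level = 1)))
  segs <- segmentSyllables(spec)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSegments(segs, "recA", frameShift(spec), path)
  df <- read.csv(path)
  expect_named(df, c("recording_id", "start_frame", "end_frame",
                     "start_s", "end_s", "peak_db"))
  expect_equal(df$start_s, df$start_frame * 0.010)
})
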