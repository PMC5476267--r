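#' Magnitude spectrogram (Hamming-windowed STFT)
#'
#' Computes the short-time Fourier magnitude of a mono signal with a
#' Hamming analysis window (default 20 ms) and frame shift (default
#' 10 ms), keeping the non-redundant half of the spectrum
#' (F = nFFT/2 + 1 bins). The number of frames is
#' \code{floor((N - win) / hop) + 1}.
#'
#' @param x an \linkS4class{AudioSignal}.
#' @param window analysis window length in seconds.
#' @param shift frame shift in seconds.
#' @param nFFT FFT size; defaults to the next power of two above the
#'   window length in samples.
#' @return a \linkS4class{Spectrogram}.
#' @export
magnitudeSpectrogram <- function(x, window = 0.020, shift = 0.010,
                                 nFFT = NULL) {
  stopifnot(methods::is(x, "AudioSignal"))
  fs <- x@sampleRate
  win <- round(window * fs)
  hop <- round(shift * fs)
  if (length(x@samples) < win) {
    stop(sprintf("signal too short: %d samples < one %d-sample window",
                 length(x@samples), win))
  }
  if (is.null(nFFT)) nFFT <- 2^ceiling(log2(win))
  if (nFFT < win) stop("nFFT must be at least the window length in samples")
  nT <- (length(x@samples) - win) %/% hop + 1L
  w <- signal::hamming(win)
  starts <- (seq_len(nT) - 1L) * hop
  frames <- matrix(0, nrow = nFFT, ncol = nT)
  idx <- outer(seq_len(win), starts, "+")
  frames[seq_len(win), ] <- x@samples[idx] * w
  V <- Mod(stats::mvfft(frames))[seq_len(nFFT / 2 + 1), , drop = FALSE]
  methods::new("Spectrogram", mag = V,
               freqs = (0:(nFFT / 2)) * fs / nFFT,
               frameShift = hop / fs, windowLength = win / fs,
               sampleRate = fs)
}

#' Segment a spectrogram into syllables
#'
#' Detects syllables as spectral pulses on the per-frame maximum-magnitude
#' trace, expressed in dB relative to the global maximum. The trace is
#' iteratively peak-stripped: the loudest unconsumed frame seeds a segment
#' that extends left and right while the trace stays above (peak -
#' \code{thresholdDb}); consumed frames are removed and the process repeats
#' until the loudest remaining frame falls below (global maximum -
#' \code{thresholdDb}). Segments shorter than \code{minFrames} are
#' discarded.
#'
#' @param spec a \linkS4class{Spectrogram}.
#' @param thresholdDb detection threshold in dB below the peak (default 20).
#' @param minFrames minimum segment length in frames (default 3).
#' @return a data.frame with columns \code{startFrame} (0-based,
#'   inclusive), \code{endFrame} (0-based, exclusive) and \code{peakDb}
#'   (dB relative to the global maximum), sorted by \code{startFrame};
#'   zero rows when nothing exceeds the threshold.
#' @export
segmentSyllables <- function(spec, thresholdDb = 20, minFrames = 3) {
  stopifnot(methods::is(spec, "Spectrogram"))
  V <- spec@mag
  nT <- ncol(V)
  if (nT < minFrames) stop("spectrogram has fewer than minFrames frames")
  trace <- apply(V, 2, max)
  gmax <- max(trace)
  empty <- data.frame(startFrame = integer(0), endFrame = integer(0),
                      peakDb = numeric(0))
  if (gmax <= 0) return(empty)
  db <- 20 * log10(pmax(trace, .EPS * gmax) / gmax)

  consumed <- rep(FALSE, nT)
  out <- list()
  repeat {
    cand <- which(!consumed)
    if (length(cand) == 0L) break
    p <- cand[which.max(db[cand])]
    if (db[p] < -thresholdDb) break
    lim <- db[p] - thresholdDb
    lo <- p
    while (lo > 1L && !consumed[lo - 1L] && db[lo - 1L] > lim) lo <- lo - 1L
    hi <- p
    while (hi < nT && !consumed[hi + 1L] && db[hi + 1L] > lim) hi <- hi + 1L
    if (hi - lo + 1L >= minFrames) {
      out[[length(out) + 1L]] <- c(lo - 1L, hi, db[p])
    }
    consumed[lo:hi] <- TRUE
  }
  if (length(out) == 0L) return(empty)
  m <- do.call(rbind, out)
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(startFrame = as.integer(m[, 1]), endFrame = as.integer(m[, 2]),
             peakDb = m[, 3])
}

#' Write a syllable segment table to CSV
#'
#' @param segments data.frame as returned by [segmentSyllables()].
#' @param recordingId identifier recorded in the first column.
#' @param frameShift frame shift in seconds, used to add start/end times.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSegments <- function(segments, recordingId, frameShift, path) {
  df <- data.frame(recording_id = rep(recordingId, nrow(segments)),
                   start_frame = segments$startFrame,
                   end_frame = segments$endFrame,
                   start_s = segments$startFrame * frameShift,
                   end_s = segments$endFrame * frameShift,
                   peak_db = segments$peakDb)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
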