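#' Read a WAV file as a mono AudioSignal
#'
#' Reads a RIFF/WAVE file (PCM 16/24/32-bit or IEEE float 32-bit, mono or
#' multi-channel), averages channels to mono, and resamples to
#' \code{targetRate} by polyphase filtering when the file rate differs.
#'
#' @param path path to a WAV file.
#' @param targetRate desired sampling rate in Hz (default 22050, the rate
#'   all analysis parameters are specified at).
#' @return an \linkS4class{AudioSignal} at \code{targetRate}.
#' @seealso [writeAudio()], [bandpassFilter()], [magnitudeSpectrogram()]
#' @export
readAudio <- function(path, targetRate = 22050) {
  if (!file.exists(path)) stop("cannot read audio file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  tag <- function() {
    r <- readBin(con, "raw", 4)
    if (length(r) < 4 || any(r == 0)) "" else rawToChar(r)
  }
  if (!identical(tag(), "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(tag(), "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  data <- NULL
  repeat {
    id <- tag()
    if (identical(id, "")) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format = sum(as.integer(raw[1:2]) * c(1, 256)),
        channels = sum(as.integer(raw[3:4]) * c(1, 256)),
        rate = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(raw[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV file: ", path)
  if (length(data) == 0) stop("empty audio in file: ", path)

  bytes <- fmt$bits %/% 8
  n <- length(data) %/% bytes
  x <- if (fmt$format == 3 && fmt$bits == 32) {
    readBin(data, "double", n, 4, endian = "little")
  } else if (fmt$format == 1 && fmt$bits == 16) {
    readBin(data, "integer", n, 2, signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 1 && fmt$bits == 24) {
    m <- matrix(as.integer(data[seq_len(n * 3)]), nrow = 3)
    v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
    ifelse(v >= 8388608, v - 16777216, v) / 8388608
  } else if (fmt$format == 1 && fmt$bits == 32) {
    readBin(data, "integer", n, 4, endian = "little") / 2147483648
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bit)",
                 fmt$format, fmt$bits))
  }

  if (fmt$channels > 1) {
    nf <- length(x) %/% fmt$channels
    x <- rowMeans(matrix(x[seq_len(nf * fmt$channels)],
                         ncol = fmt$channels, byrow = TRUE))
  }
  if (length(x) == 0) stop("empty audio in file: ", path)

  if (fmt$rate != targetRate) {
    g <- .gcd(targetRate, fmt$rate)
    x <- signal::resample(x, targetRate / g, fmt$rate / g)
  }
  methods::new("AudioSignal", samples = as.numeric(x),
               sampleRate = targetRate)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Write a mono AudioSignal to a 16-bit PCM WAV file
#'
#' @param x an \linkS4class{AudioSignal}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAudio <- function(x, path) {
  stopifnot(methods::is(x, "AudioSignal"))
  s <- x@samples
  peak <- max(abs(s), 1)
  if (peak > 1) s <- s / peak     # avoid wrap-around clipping
  pcm <- as.integer(pmax(pmin(round(s * 32768), 32767), -32768))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")      # PCM
  writeBin(1L, con, 2, endian = "little")      # mono
  writeBin(as.integer(x@sampleRate), con, 4, endian = "little")
  writeBin(as.integer(x@sampleRate * 2), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")      # block align
  writeBin(16L, con, 2, endian = "little")     # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

#' Band-pass filter an audio signal
#'
#' Applies a Butterworth band-pass filter forward and backward (zero
#' phase). Bird vocalizations concentrate in 1-10.5 kHz; the defaults
#' suppress low-frequency ambient noise and out-of-band interference.
#'
#' @param x an \linkS4class{AudioSignal}.
#' @param low,high pass-band edges in Hz.
#' @param order Butterworth prototype order (default 4; the resulting
#'   band-pass has twice this order, and the forward-backward pass
#'   doubles the effective attenuation again).
#' @return a filtered \linkS4class{AudioSignal} of the same length and rate.
#' @export
bandpassFilter <- function(x, low = 1000, high = 10500, order = 4) {
  stopifnot(methods::is(x, "AudioSignal"))
  nyq <- x@sampleRate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop(sprintf(
      "cannot design band-pass filter: need 0 < low < high < Nyquist (%g Hz)",
      nyq))
  }
  if (order < 1) stop("'order' must be a positive integer")
  bt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  y <- signal::filtfilt(bt, x@samples)
  methods::new("AudioSignal", samples = as.numeric(y),
               sampleRate = x@sampleRate)
}
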