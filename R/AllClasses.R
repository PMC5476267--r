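#' @import methods
NULL

#' Mono audio signal
#'
#' Container for a single-channel, uniformly sampled audio signal.
#'
#' @slot samples numeric vector of amplitudes (dimensionless).
#' @slot sampleRate sampling rate in Hz.
#' @exportClass AudioSignal
setClass("AudioSignal",
  representation(samples = "numeric", sampleRate = "numeric"),
  validity = function(object) {
    if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
        object@sampleRate <= 0) {
      return("sampleRate must be a single positive finite number")
    }
    if (length(object@samples) < 1L) return("samples must be non-empty")
    if (any(!is.finite(object@samples))) return("samples must be finite")
    TRUE
  }
)

#' Magnitude spectrogram
#'
#' Non-negative short-time Fourier magnitude matrix V (F frequency bins x
#' T frames) together with its analysis-grid metadata.
#'
#' @slot mag non-negative matrix, F bins x T frames.
#' @slot freqs centre frequency (Hz) of each bin, strictly increasing from
#'   0 to Nyquist.
#' @slot frameShift frame shift (hop) in seconds.
#' @slot windowLength analysis window length in seconds.
#' @slot sampleRate sampling rate (Hz) of the source signal.
#' @exportClass Spectrogram
setClass("Spectrogram",
  representation(mag = "matrix", freqs = "numeric", frameShift = "numeric",
                 windowLength = "numeric", sampleRate = "numeric"),
  validity = function(object) {
    if (any(object@mag < 0)) return("magnitude entries must be >= 0")
    if (nrow(object@mag) != length(object@freqs)) {
      return("freqs length must equal the number of rows of mag")
    }
    if (length(object@freqs) > 1L && any(diff(object@freqs) <= 0)) {
      return("freqs must be strictly increasing")
    }
    if (object@frameShift <= 0 || object@windowLength <= 0) {
      return("frameShift and windowLength must be positive")
    }
    TRUE
  }
)

#' Auditory filter bank
#'
#' A bank of K spectral filters (rows) over F frequency bins, either the
#' conventional triangular mel-scaled bank or one learned by NMF from bird
#' sound spectrograms.
#'
#' @slot filters non-negative matrix, K filters x F bins.
#' @slot kind either "mel" or "nmf".
#' @slot freqs bin centre frequencies in Hz.
#' @exportClass FilterBank
setClass("FilterBank",
  representation(filters = "matrix", kind = "character", freqs = "numeric"),
  validity = function(object) {
    if (any(object@filters < 0)) return("filters must be non-negative")
    if (!object@kind %in% c("mel", "nmf")) {
      return("kind must be 'mel' or 'nmf'")
    }
    if (ncol(object@filters) != length(object@freqs)) {
      return("freqs length must equal the number of filter bins")
    }
    if (any(rowSums(object@filters) <= 0)) {
      return("every filter must have at least one positive entry")
    }
    TRUE
  }
)

#' KL-NMF factorization model
#'
#' Result of factorizing a non-negative matrix V (F x T) as W H with W
#' (F x K) holding spectral basis vectors and H (K x T) the activation
#' coefficients, by minimizing the generalized Kullback-Leibler divergence.
#'
#' @slot W non-negative basis matrix, F x K.
#' @slot H non-negative activation matrix, K x T.
#' @slot divergenceTrace KL divergence after each multiplicative update
#'   sweep; non-increasing.
#' @slot config list recording K, restarts, iterations, tolerance and seed.
#' @exportClass NMFModel
setClass("NMFModel",
  representation(W = "matrix", H = "matrix", divergenceTrace = "numeric",
                 config = "list"),
  validity = function(object) {
    if (any(object@W < 0) || any(object@H < 0)) {
      return("W and H must be non-negative")
    }
    if (ncol(object@W) != nrow(object@H)) {
      return("inner dimensions of W and H must agree")
    }
    tr <- object@divergenceTrace
    tr <- tr[is.finite(tr)]
    if (length(tr) > 1L && any(diff(tr) > 1e-8 * (abs(tr[-length(tr)]) + 1))) {
      return("divergenceTrace must be non-increasing")
    }
    TRUE
  }
)

#' Per-class spectral basis vector model
#'
#' Concatenation of per-species NMF bases: column block i (columns
#' (i-1)*K+1 ... i*K) holds the K spectral basis vectors of class i.
#'
#' @slot Wbs non-negative matrix, F x (K*C).
#' @slot classLabels ordered class names (length C).
#' @slot KPerClass number of basis vectors per class.
#' @exportClass SbvModel
setClass("SbvModel",
  representation(Wbs = "matrix", classLabels = "character",
                 KPerClass = "integer"),
  validity = function(object) {
    if (any(object@Wbs < 0)) return("Wbs must be non-negative")
    if (ncol(object@Wbs) !=
        object@KPerClass * length(object@classLabels)) {
      return("Wbs must have K * C columns")
    }
    if (object@KPerClass < 1L) return("KPerClass must be >= 1")
    TRUE
  }
)

#' Per-frame short-time feature matrix
#'
#' @slot X feature matrix, T frames x D features.
#' @slot layout ordered column names (e.g. c1..c12, logE, hcc1..hcc13,
#'   gnmf, d_*).
#' @exportClass ShortTimeFeatures
setClass("ShortTimeFeatures",
  representation(X = "matrix", layout = "character"),
  validity = function(object) {
    if (ncol(object@X) != length(object@layout)) {
      return("layout length must equal the number of feature columns")
    }
    if (any(!is.finite(object@X))) return("features must be finite")
    TRUE
  }
)

#' Synthetic species description
#'
#' Spectral and temporal parameters of one synthetic bird species: syllables
#' are amplitude-enveloped linear chirps at the species' basis frequencies.
#'
#' @slot name species label.
#' @slot basisFreqs chirp centre frequencies (Hz), inside (1000, 10500).
#' @slot basisWidths spectral widths (Hz) controlling relative component
#'   amplitudes.
#' @slot syllableDurationRange min/max syllable duration (s).
#' @slot syllableRate mean syllables per second.
#' @slot chirpSlopeRange min/max chirp slope (Hz/s).
#' @exportClass SpeciesSpec
setClass("SpeciesSpec",
  representation(name = "character", basisFreqs = "numeric",
                 basisWidths = "numeric", syllableDurationRange = "numeric",
                 syllableRate = "numeric", chirpSlopeRange = "numeric"),
  validity = function(object) {
    if (any(object@basisFreqs <= 1000 | object@basisFreqs >= 10500)) {
      return("basisFreqs must lie inside (1000, 10500) Hz")
    }
    if (object@syllableRate <= 0) return("syllableRate must be positive")
    if (length(object@syllableDurationRange) != 2L ||
        diff(object@syllableDurationRange) < 0) {
      return("syllableDurationRange must be (min, max)")
    }
    TRUE
  }
)

#' Labeled synthetic dataset
#'
#' @slot recordings list of AudioSignal objects.
#' @slot labels species label per recording.
#' @slot boundaries list of data.frames (startFrame, endFrame) of true
#'   syllable boundaries on the standard analysis grid.
#' @slot specs list of SpeciesSpec objects used.
#' @slot seed integer seed the dataset was generated from.
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  representation(recordings = "list", labels = "character",
                 boundaries = "list", specs = "list", seed = "integer"),
  validity = function(object) {
    n <- length(object@recordings)
    if (length(object@labels) != n || length(object@boundaries) != n) {
      return("labels and boundaries must match recordings in length")
    }
    specNames <- vapply(object@specs, function(s) s@name, character(1))
    if (!all(object@labels %in% specNames)) {
      return("labels must be drawn from the species specs")
    }
    TRUE
  }
)

#' Trained SVM species classifier
#'
#' One-vs-one RBF support vector machine on z-score normalized segmental
#' features, with the hyperparameters selected by inner cross-validation.
#'
#' @slot center per-feature training means.
#' @slot scale per-feature training standard deviations (floored).
#' @slot svm fitted e1071::svm object.
#' @slot classes ordered class names.
#' @slot hyperparams named numeric vector with elements cost and gamma.
#' @exportClass ClassifierModel
setClass("ClassifierModel",
  representation(center = "numeric", scale = "numeric", svm = "ANY",
                 classes = "character", hyperparams = "numeric"),
  validity = function(object) {
    if (length(object@center) != length(object@scale)) {
      return("center and scale must have equal length")
    }
    if (length(object@classes) < 1L) return("classes must be non-empty")
    TRUE
  }
)

#' Cross-validated evaluation report
#'
#' @slot foldAccuracy per-fold recording-level accuracy (percent).
#' @slot speciesAccuracy per-species accuracy (percent).
#' @slot confusion column-normalized confusion matrix (percent), columns =
#'   true class, rows = hypothesized class, averaged over folds.
#' @slot overallAccuracy overall recording-level accuracy (percent).
#' @slot folds per-fold bookkeeping (train/test indices, fold accuracy).
#' @slot frontend front-end identifier the report was produced with.
#' @slot config resolved configuration list.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(foldAccuracy = "numeric", speciesAccuracy = "numeric",
                 confusion = "matrix", overallAccuracy = "numeric",
                 folds = "list", frontend = "character", config = "list"),
  validity = function(object) {
    acc <- c(object@foldAccuracy, object@speciesAccuracy,
             object@overallAccuracy)
    if (any(acc < -1e-9 | acc > 100 + 1e-9)) {
      return("accuracies must lie in [0, 100]")
    }
    cs <- colSums(object@confusion)
    if (length(cs) && any(abs(cs - 100) > 0.1)) {
      return("confusion matrix columns must sum to 100")
    }
    TRUE
  }
)
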