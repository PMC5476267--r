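#' Accessors for birdnmf S4 classes
#'
#' Small accessor generics: \code{samples} and \code{sampleRate} for
#' \linkS4class{AudioSignal}; \code{specMatrix}, \code{binFreqs},
#' \code{frameShift} and \code{nFrames} for \linkS4class{Spectrogram};
#' \code{basisMatrix}, \code{activations} and \code{divergenceTrace} for
#' \linkS4class{NMFModel}; \code{filterMatrix} for
#' \linkS4class{FilterBank}; \code{sbvMatrix} and \code{classLabels} for
#' \linkS4class{SbvModel}; \code{featureMatrix} and \code{featureLayout}
#' for \linkS4class{ShortTimeFeatures}.
#'
#' @param x an object of the documented class.
#' @return The slot content named by the accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("specMatrix", function(x) standardGeneric("specMatrix"))
#' @rdname accessors
#' @export
setGeneric("binFreqs", function(x) standardGeneric("binFreqs"))
#' @rdname accessors
#' @export
setGeneric("frameShift", function(x) standardGeneric("frameShift"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))
#' @rdname accessors
#' @export
setGeneric("activations", function(x) standardGeneric("activations"))
#' @rdname accessors
#' @export
setGeneric("divergenceTrace", function(x) standardGeneric("divergenceTrace"))
#' @rdname accessors
#' @export
setGeneric("filterMatrix", function(x) standardGeneric("filterMatrix"))
#' @rdname accessors
#' @export
setGeneric("sbvMatrix", function(x) standardGeneric("sbvMatrix"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("featureLayout", function(x) standardGeneric("featureLayout"))

#' @rdname accessors
setMethod("samples", "AudioSignal", function(x) x@samples)
#' @rdname accessors
setMethod("sampleRate", "AudioSignal", function(x) x@sampleRate)
#' @rdname accessors
setMethod("sampleRate", "Spectrogram", function(x) x@sampleRate)
#' @rdname accessors
setMethod("specMatrix", "Spectrogram", function(x) x@mag)
#' @rdname accessors
setMethod("binFreqs", "Spectrogram", function(x) x@freqs)
#' @rdname accessors
setMethod("binFreqs", "FilterBank", function(x) x@freqs)
#' @rdname accessors
setMethod("frameShift", "Spectrogram", function(x) x@frameShift)
#' @rdname accessors
setMethod("nFrames", "Spectrogram", function(x) ncol(x@mag))
#' @rdname accessors
setMethod("nFrames", "ShortTimeFeatures", function(x) nrow(x@X))
#' @rdname accessors
setMethod("basisMatrix", "NMFModel", function(x) x@W)
#' @rdname accessors
setMethod("activations", "NMFModel", function(x) x@H)
#' @rdname accessors
setMethod("divergenceTrace", "NMFModel", function(x) x@divergenceTrace)
#' @rdname accessors
setMethod("filterMatrix", "FilterBank", function(x) x@filters)
#' @rdname accessors
setMethod("sbvMatrix", "SbvModel", function(x) x@Wbs)
#' @rdname accessors
setMethod("classLabels", "SbvModel", function(x) x@classLabels)
#' @rdname accessors
setMethod("classLabels", "ClassifierModel", function(x) x@classes)
#' @rdname accessors
setMethod("featureMatrix", "ShortTimeFeatures", function(x) x@X)
#' @rdname accessors
setMethod("featureLayout", "ShortTimeFeatures", function(x) x@layout)

setMethod("show", "AudioSignal", function(object) {
  cat(sprintf("AudioSignal: %d samples at %g Hz (%.3f s)\n",
              length(object@samples), object@sampleRate,
              length(object@samples) / object@sampleRate))
})

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf(
    "Spectrogram: %d bins x %d frames (win %.0f ms, shift %.0f ms, %g Hz)\n",
    nrow(object@mag), ncol(object@mag), 1000 * object@windowLength,
    1000 * object@frameShift, object@sampleRate))
})

setMethod("show", "FilterBank", function(object) {
  cat(sprintf("FilterBank (%s): %d filters x %d bins\n",
              object@kind, nrow(object@filters), ncol(object@filters)))
})

setMethod("show", "NMFModel", function(object) {
  tr <- object@divergenceTrace
  cat(sprintf("NMFModel: W %d x %d, H %d x %d; %d update sweeps, final KL %.4g\n",
              nrow(object@W), ncol(object@W), nrow(object@H), ncol(object@H),
              length(tr), if (length(tr)) tr[length(tr)] else NA_real_))
})

setMethod("show", "SbvModel", function(object) {
  cat(sprintf("SbvModel: %d classes x %d SBVs each (%d x %d)\n",
              length(object@classLabels), object@KPerClass,
              nrow(object@Wbs), ncol(object@Wbs)))
})

setMethod("show", "ShortTimeFeatures", function(object) {
  cat(sprintf("ShortTimeFeatures: %d frames x %d features [%s%s]\n",
              nrow(object@X), ncol(object@X),
              paste(utils::head(object@layout, 4), collapse = ", "),
              if (length(object@layout) > 4) ", ..." else ""))
})

setMethod("show", "SpeciesSpec", function(object) {
  cat(sprintf("SpeciesSpec '%s': components at %s Hz, %.1f syll/s\n",
              object@name,
              paste(round(object@basisFreqs), collapse = "/"),
              object@syllableRate))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset: %d recordings, %d species (seed %d)\n",
              length(object@recordings),
              length(unique(object@labels)), object@seed))
})

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf("ClassifierModel: %d classes, %d features, C = %g, gamma = %g\n",
              length(object@classes), length(object@center),
              object@hyperparams[["cost"]], object@hyperparams[["gamma"]]))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport [%s]: overall accuracy %.2f%% over %d folds\n",
              object@frontend, object@overallAccuracy,
              length(object@foldAccuracy)))
  cat("  per-fold: ", paste(sprintf("%.1f", object@foldAccuracy),
                            collapse = " "), "\n", sep = "")
})
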