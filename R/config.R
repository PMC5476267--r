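#' Default pipeline configuration
#'
#' Returns the full configuration of the classification pipeline as a
#' nested list. The defaults are the standard configuration of the pipeline:
#' 22.05 kHz audio, 1-10.5 kHz 4th-order Butterworth band-pass, 20 ms
#' Hamming window with 10 ms shift (nFFT = 512), 20 dB segmentation
#' threshold, 40-filter banks, K = 4 SBVs per class, NMF with 10 random
#' restarts and at most 200 multiplicative update sweeps, an RBF SVM
#' selected by 5-fold inner cross-validation, and 6-fold outer
#' evaluation.
#'
#' @param ... named overrides of the form \code{section.key = value},
#'   e.g. \code{pipelineConfig(nmf.maxIter = 100)}.
#' @return nested named list of configuration sections.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    audio = list(rate = 22050, low = 1000, high = 10500, order = 4),
    spectrogram = list(window = 0.020, shift = 0.010, nFFT = 512),
    segmentation = list(thresholdDb = 20, minFrames = 3),
    frontend = list(nCeps = 12, nCepsHcc = 13, KFilterbank = 40,
                    KPerClass = 4, withGnmf = TRUE, deltaWindow = 2),
    nmf = list(nRestarts = 10, maxIter = 200, tol = 1e-6, maxFrames = 4000),
    classifier = list(innerFolds = 5),
    evaluation = list(folds = 6)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2 || is.null(cfg[[parts[1]]])) {
      stop("unknown configuration key: ", nm)
    }
    cfg[[parts[1]]][[parts[2]]] <- dots[[nm]]
  }
  cfg
}

#' Known front-end identifiers
#'
#' @return character vector of the supported front-end names.
#' @export
frontendChoices <- function() {
  c("mfcc", "nmf_cc", "h_cc", "mfcc+h_cc", "nmf_cc+h_cc")
}
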