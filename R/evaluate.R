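# Pipeline glue: per-recording preprocessing, front-end dispatch, and the
# stratified K-fold evaluation harness with per-recording majority voting.

# Band-pass filter, spectrogram and syllable segmentation for one recording.
.prepareRecording <- function(audio, config) {
  filtered <- bandpassFilter(audio, low = config$audio$low,
                             high = config$audio$high,
                             order = config$audio$order)
  spec <- magnitudeSpectrogram(filtered, window = config$spectrogram$window,
                               shift = config$spectrogram$shift,
                               nFFT = config$spectrogram$nFFT)
  segs <- segmentSyllables(spec, thresholdDb = config$segmentation$thresholdDb,
                           minFrames = config$segmentation$minFrames)
  list(spec = spec, segments = segs)
}

.needsCepstral <- function(frontend) {
  frontend %in% c("mfcc", "nmf_cc", "mfcc+h_cc", "nmf_cc+h_cc")
}
.needsNmfBank <- function(frontend) {
  frontend %in% c("nmf_cc", "nmf_cc+h_cc")
}
.needsSbv <- function(frontend) {
  frontend %in% c("h_cc", "mfcc+h_cc", "nmf_cc+h_cc")
}

# Short-time features for a set of prepared recordings under a given
# front-end, using previously learned artifacts (bank and/or sbv).
# Activation inference is batched over the recordings (column-separable
# updates make this equivalent to per-recording inference). Returns a
# list parallel to `prep`.
.shortTimeFeatureSet <- function(prep, frontend, deltas, bank, sbv, config,
                                 seed) {
  fe <- config$frontend
  specs <- lapply(prep, `[[`, "spec")
  cc <- if (.needsCepstral(frontend)) {
    lapply(specs, cepstralFeatures, bank = bank, nCeps = fe$nCeps)
  }
  hcc <- if (.needsSbv(frontend)) {
    .hccFeaturesBatch(specs, sbv, nCeps = fe$nCepsHcc,
                      withGnmf = fe$withGnmf,
                      maxIter = config$nmf$maxIter,
                      tol = config$nmf$tol, seed = seed)
  }
  lapply(seq_along(prep), function(i) {
    feats <- if (!is.null(cc) && !is.null(hcc)) {
      concatFeatures(cc[[i]], hcc[[i]])
    } else if (!is.null(cc)) cc[[i]] else hcc[[i]]
    if (deltas) feats <- appendDeltas(feats, window = fe$deltaWindow)
    feats
  })
}

.datasetParts <- function(dataset) {
  if (methods::is(dataset, "SyntheticDataset")) {
    list(recordings = dataset@recordings, labels = dataset@labels)
  } else {
    stopifnot(is.list(dataset), !is.null(dataset$recordings),
              !is.null(dataset$labels))
    list(recordings = dataset$recordings,
         labels = as.character(dataset$labels))
  }
}

# Learn the front-end artifacts (filter bank, SBV model) from a set of
# prepared recordings.
.learnFrontend <- function(prep, labels, frontend, config, seed) {
  fe <- config$frontend
  nm <- config$nmf
  bank <- NULL
  sbv <- NULL
  if (.needsCepstral(frontend)) {
    bank <- if (.needsNmfBank(frontend)) {
      learnNmfFilterBank(lapply(prep, `[[`, "spec"), K = fe$KFilterbank,
                         maxFrames = nm$maxFrames, nRestarts = nm$nRestarts,
                         maxIter = nm$maxIter, tol = nm$tol,
                         seed = .childSeed(seed, "bank"))
    } else {
      melFilterBank(nFilters = fe$KFilterbank, nFFT = config$spectrogram$nFFT,
                    rate = config$audio$rate)
    }
  }
  if (.needsSbv(frontend)) {
    byClass <- split(lapply(prep, `[[`, "spec"), labels)
    sbv <- learnClassSbvs(byClass, K = fe$KPerClass, maxFrames = nm$maxFrames,
                          nRestarts = nm$nRestarts, maxIter = nm$maxIter,
                          tol = nm$tol, seed = .childSeed(seed, "sbv"))
  }
  list(bank = bank, sbv = sbv)
}

#' Extract segmental features for a whole dataset
#'
#' Runs the full front-end (preprocessing, short-time feature extraction,
#' temporal integration) over every recording, learning the NMF filter
#' bank and/or SBV model from the dataset itself. Intended for feature
#' dumps and exploration; [kfoldEvaluate()] learns its artifacts from
#' training folds only.
#'
#' @param dataset a \linkS4class{SyntheticDataset} or a list with elements
#'   \code{recordings} (list of \linkS4class{AudioSignal}) and
#'   \code{labels}.
#' @param frontend one of [frontendChoices()].
#' @param deltas append first-derivative features (default FALSE).
#' @param config pipeline configuration, see [pipelineConfig()].
#' @param seed integer seed.
#' @return data.frame with columns \code{recording_id},
#'   \code{syllable_index}, \code{label}, \code{start_frame},
#'   \code{end_frame}, then the 3 x D named segmental features.
#' @export
extractDatasetFeatures <- function(dataset, frontend = "mfcc",
                                   deltas = FALSE,
                                   config = pipelineConfig(), seed = 1) {
  frontend <- match.arg(frontend, frontendChoices())
  parts <- .datasetParts(dataset)
  prep <- lapply(parts$recordings, .prepareRecording, config = config)
  art <- .learnFrontend(prep, parts$labels, frontend, config, seed)
  featsList <- .shortTimeFeatureSet(prep, frontend, deltas, art$bank,
                                    art$sbv, config,
                                    .childSeed(seed, "hcc"))
  rows <- list()
  for (i in seq_along(prep)) {
    feats <- featsList[[i]]
    segs <- prep[[i]]$segments
    M <- integrateSyllables(feats, segs)
    if (nrow(M) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      recording_id = i, syllable_index = seq_len(nrow(M)),
      label = parts$labels[i], start_frame = segs$startFrame,
      end_frame = segs$endFrame, M, check.names = FALSE)
  }
  if (length(rows) == 0) {
    M <- integrateSyllables(featsList[[1]],
                            prep[[1]]$segments[0, , drop = FALSE])
    out <- data.frame(recording_id = integer(0), syllable_index = integer(0),
                      label = character(0), start_frame = integer(0),
                      end_frame = integer(0), check.names = FALSE)
    return(cbind(out, as.data.frame(M)))
  }
  do.call(rbind, rows)
}

#' Stratified K-fold evaluation of a front-end
#'
#' Splits the recordings into K stratified folds. In each fold, the NMF
#' filter bank and/or per-class SBV model are learned from the training
#' recordings only, segmental features are extracted, an RBF SVM is
#' selected by inner cross-validation and trained on the training
#' syllables, and each test recording is classified by majority voting
#' over its syllables. Reports per-fold, per-species and overall
#' recording-level accuracies plus the column-normalized confusion matrix
#' (columns = true class, percent, averaged over folds).
#'
#' @inheritParams extractDatasetFeatures
#' @param K number of outer folds (default 6); every class needs at least
#'   K recordings.
#' @param grid SVM hyperparameter grid (see [defaultHyperGrid()]).
#' @return an \linkS4class{EvaluationReport}.
#' @export
kfoldEvaluate <- function(dataset, frontend = "nmf_cc", deltas = TRUE,
                          K = 6, grid = defaultHyperGrid(),
                          config = pipelineConfig(), seed = 1) {
  frontend <- match.arg(frontend, frontendChoices())
  parts <- .datasetParts(dataset)
  labels <- parts$labels
  classes <- sort(unique(labels))
  nC <- length(classes)
  prep <- lapply(parts$recordings, .prepareRecording, config = config)
  fold <- .stratifiedFolds(labels, K, seed)

  confSum <- matrix(0, nC, nC, dimnames = list(classes, classes))
  confN <- matrix(0, nC, nC, dimnames = list(classes, classes))
  foldAcc <- numeric(K)
  foldInfo <- vector("list", K)
  nTestTotal <- 0L
  nCorrectTotal <- 0L

  for (f in seq_len(K)) {
    trainIdx <- which(fold != f)
    testIdx <- which(fold == f)
    art <- .learnFrontend(prep[trainIdx], labels[trainIdx], frontend, config,
                          .childSeed(seed, "fold", f))
    feats <- .shortTimeFeatureSet(prep, frontend, deltas, art$bank,
                                  art$sbv, config,
                                  .childSeed(seed, "hcc", f))
    trainX <- list(); trainY <- character(0)
    for (i in trainIdx) {
      M <- integrateSyllables(feats[[i]], prep[[i]]$segments)
      if (nrow(M) == 0) next
      trainX[[length(trainX) + 1L]] <- M
      trainY <- c(trainY, rep(labels[i], nrow(M)))
    }
    model <- trainClassifier(do.call(rbind, trainX), trainY, grid = grid,
                             innerFolds = config$classifier$innerFolds,
                             seed = .childSeed(seed, "svm", f))
    predicted <- character(length(testIdx))
    for (j in seq_along(testIdx)) {
      i <- testIdx[j]
      M <- integrateSyllables(feats[[i]], prep[[i]]$segments)
      predicted[j] <- if (nrow(M) == 0) NA_character_ else
        classifyRecording(model, M)
    }
    truth <- labels[testIdx]
    correct <- sum(!is.na(predicted) & predicted == truth)
    foldAcc[f] <- 100 * correct / length(testIdx)
    nTestTotal <- nTestTotal + length(testIdx)
    nCorrectTotal <- nCorrectTotal + correct

    cnt <- table(factor(predicted, levels = classes),
                 factor(truth, levels = classes))
    colTot <- colSums(cnt)
    for (cc in which(colTot > 0)) {
      confSum[, cc] <- confSum[, cc] + 100 * cnt[, cc] / colTot[cc]
      confN[, cc] <- confN[, cc] + 1
    }
    foldInfo[[f]] <- list(train = trainIdx, test = testIdx,
                          accuracy = foldAcc[f],
                          hyperparams = model@hyperparams,
                          nUnclassified = sum(is.na(predicted)))
  }
  confusion <- confSum / pmax(confN, 1)
  speciesAcc <- diag(confusion)
  names(speciesAcc) <- classes
  methods::new("EvaluationReport",
               foldAccuracy = foldAcc, speciesAccuracy = speciesAcc,
               confusion = confusion,
               overallAccuracy = 100 * nCorrectTotal / nTestTotal,
               folds = foldInfo,
               frontend = paste0(frontend, if (deltas) "+delta" else ""),
               config = c(config, list(K = K, seed = seed,
                                       frontendName = frontend,
                                       deltas = deltas)))
}
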