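#' Default RBF-SVM hyperparameter grid
#'
#' LIBSVM-style log2 grid: cost in 2^(-3..7), gamma in 2^(-7..3), both in
#' steps of 2.
#'
#' @return data.frame with columns \code{cost} and \code{gamma}.
#' @export
defaultHyperGrid <- function() {
  expand.grid(cost = 2^seq(-3, 7, by = 2), gamma = 2^seq(-7, 3, by = 2),
              KEEP.OUT.ATTRS = FALSE)
}

# Seeded stratified fold assignment: within each class, recordings are
# shuffled and dealt round-robin into K folds.
.stratifiedFolds <- function(labels, K, seed) {
  fold <- integer(length(labels))
  withr::with_seed(.childSeed(seed, "folds"), {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < K) {
        stop(sprintf("class '%s' has %d samples, fewer than %d folds",
                     cls, length(idx), K))
      }
      fold[sample(idx)] <- rep_len(seq_len(K), length(idx))
    }
  })
  fold
}

#' Train an RBF-SVM species classifier with inner-CV model selection
#'
#' Fits a z-score normalizer on the training data, selects the RBF kernel
#' parameters (cost, gamma) by stratified \code{innerFolds}-fold
#' cross-validation over \code{grid} (ties resolved to smaller cost, then
#' smaller gamma), and refits a one-vs-one RBF SVM on all training data
#' with the selected pair.
#'
#' @param X numeric matrix of segmental feature vectors (rows = syllables).
#' @param labels class label per row.
#' @param grid hyperparameter grid (see [defaultHyperGrid()]).
#' @param innerFolds inner cross-validation folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return a \linkS4class{ClassifierModel}.
#' @export
trainClassifier <- function(X, labels, grid = defaultHyperGrid(),
                            innerFolds = 5, seed = 1) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("at least 2 classes are required")
  counts <- table(labels)
  if (any(counts < innerFolds)) {
    stop(sprintf("class '%s' has fewer samples (%d) than inner folds (%d)",
                 names(counts)[which.min(counts)], min(counts), innerFolds))
  }
  center <- colMeans(X)
  scl <- pmax(apply(X, 2, stats::sd), 1e-8)
  Z <- sweep(sweep(X, 2, center), 2, scl, "/")
  y <- factor(labels, levels = classes)

  fold <- .stratifiedFolds(labels, innerFolds, seed)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(innerFolds)) {
      tr <- fold != f
      fit <- e1071::svm(Z[tr, , drop = FALSE], y[tr], type = "C-classification",
                        kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g], scale = FALSE)
      pred <- stats::predict(fit, Z[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    acc[g] <- correct / nrow(Z)
  }
  best <- order(-acc, grid$cost, grid$gamma)[1]
  fit <- e1071::svm(Z, y, type = "C-classification", kernel = "radial",
                    cost = grid$cost[best], gamma = grid$gamma[best],
                    scale = FALSE)
  methods::new("ClassifierModel", center = center, scale = scl, svm = fit,
               classes = classes,
               hyperparams = c(cost = grid$cost[best],
                               gamma = grid$gamma[best],
                               innerAccuracy = acc[best]))
}

#' Classify individual syllables
#'
#' Normalizes the segmental feature vectors with the model's training
#' statistics and predicts a class per syllable.
#'
#' @param model a \linkS4class{ClassifierModel}.
#' @param X matrix of segmental feature vectors (rows = syllables).
#' @return character vector of predicted class names.
#' @export
classifySyllables <- function(model, X) {
  X <- as.matrix(X)
  Z <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  as.character(stats::predict(model@svm, Z))
}

#' Classify a whole recording by majority voting
#'
#' Each syllable is classified independently; the recording receives the
#' most frequent syllable label. Ties are broken in favour of the class
#' earliest in the model's class ordering.
#'
#' @param model a \linkS4class{ClassifierModel}.
#' @param X matrix of the recording's syllable feature vectors (>= 1 row).
#' @return the predicted class name.
#' @export
classifyRecording <- function(model, X) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("recording has no syllable features; unclassifiable")
  votes <- classifySyllables(model, X)
  tab <- table(factor(votes, levels = model@classes))
  model@classes[which.max(tab)]   # which.max: first maximum = earliest class
}
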