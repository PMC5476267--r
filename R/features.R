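# Orthonormal DCT-II matrix (N x N). Row k+1 is
#   c_k * cos(pi * (2n + 1) * k / (2N)),  c_0 = sqrt(1/N), c_k = sqrt(2/N).
# Orthonormal, so its transpose is the inverse transform.
.dctMatrix <- function(N) {
  n <- 0:(N - 1)
  D <- sqrt(2 / N) * cos(pi * outer(n, 2 * n + 1) / (2 * N))
  D[1, ] <- sqrt(1 / N)
  D
}

.hzToMel <- function(f) 2595 * log10(1 + f / 700)
.melToHz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel-scaled filter bank
#'
#' The conventional auditory filter bank used for MFCC: \code{nFilters}
#' triangular filters with centre frequencies equally spaced on the mel
#' scale between 0 Hz and Nyquist.
#'
#' @param nFilters number of filters (default 40).
#' @param nFFT FFT size (the bank covers nFFT/2 + 1 bins).
#' @param rate sampling rate in Hz.
#' @return a \linkS4class{FilterBank} of kind \code{"mel"}.
#' @export
melFilterBank <- function(nFilters = 40, nFFT = 512, rate = 22050) {
  if (nFilters < 1) stop("nFilters must be >= 1")
  nBins <- nFFT / 2 + 1
  freqs <- (0:(nFFT / 2)) * rate / nFFT
  edges <- .melToHz(seq(0, .hzToMel(rate / 2), length.out = nFilters + 2))
  filt <- matrix(0, nFilters, nBins)
  for (k in seq_len(nFilters)) {
    lo <- edges[k]; ctr <- edges[k + 1]; hi <- edges[k + 2]
    up <- (freqs - lo) / (ctr - lo)
    down <- (hi - freqs) / (hi - ctr)
    filt[k, ] <- pmax(0, pmin(up, down))
  }
  if (any(rowSums(filt) <= 0)) {
    stop("nFilters too large for the FFT resolution: a filter covers no bin")
  }
  methods::new("FilterBank", filters = filt, kind = "mel", freqs = freqs)
}

#' Learn an auditory filter bank by NMF
#'
#' Concatenates the columns of the training spectrograms into one matrix
#' V (F x n_s) and factorizes it with [nmfDecompose()]; the K basis
#' vectors (columns of W) are returned as spectral filters, each
#' L1-normalized and sorted by peak-frequency bin. This is the
#' unsupervised NMF_CC filter bank that replaces the mel bank.
#'
#' @param specs list of \linkS4class{Spectrogram} objects with identical
#'   bin layouts.
#' @param K number of filters to learn (default 40).
#' @param maxFrames cap on the number of training frames; when the
#'   concatenated matrix is wider, a seeded random subsample of columns is
#'   used (default 4000).
#' @param nRestarts,maxIter,tol,seed passed to [nmfDecompose()].
#' @return a \linkS4class{FilterBank} of kind \code{"nmf"}.
#' @export
learnNmfFilterBank <- function(specs, K = 40, maxFrames = 4000,
                               nRestarts = 10, maxIter = 200, tol = 1e-6,
                               seed = 1) {
  if (length(specs) == 0) stop("at least one training spectrogram is required")
  V <- do.call(cbind, lapply(specs, .asMagnitude))
  freqs <- binFreqs(specs[[1]])
  if (ncol(V) > maxFrames) {
    keep <- withr::with_seed(.childSeed(seed, "sub"),
                             sort(sample.int(ncol(V), maxFrames)))
    V <- V[, keep, drop = FALSE]
  }
  fit <- nmfDecompose(V, K, nRestarts = nRestarts, maxIter = maxIter,
                      tol = tol, seed = seed)
  W <- basisMatrix(fit)
  l1 <- pmax(colSums(W), .EPS)
  W <- sweep(W, 2, l1, "/")
  ord <- order(apply(W, 2, which.max))
  methods::new("FilterBank", filters = t(W[, ord, drop = FALSE]),
               kind = "nmf", freqs = freqs)
}

#' Cepstral short-time features (MFCC / NMF_CC)
#'
#' Per frame: filter-bank outputs of the magnitude spectrum, floored log,
#' orthonormal DCT-II; coefficients C1..C\code{nCeps} are kept (C0 is
#' discarded) and the frame log-energy (log of the summed squared
#' magnitude) is appended, giving D = nCeps + 1 features. With the mel
#' bank these are MFCC; with an NMF-learned bank, NMF_CC.
#'
#' @param spec a \linkS4class{Spectrogram}.
#' @param bank a \linkS4class{FilterBank} over the same bins.
#' @param nCeps number of cepstral coefficients kept (default 12).
#' @return a \linkS4class{ShortTimeFeatures} (T x (nCeps + 1)), layout
#'   \code{c1..c<nCeps>, logE}.
#' @export
cepstralFeatures <- function(spec, bank, nCeps = 12) {
  stopifnot(methods::is(spec, "Spectrogram"), methods::is(bank, "FilterBank"))
  V <- spec@mag
  filt <- bank@filters
  if (ncol(filt) != nrow(V)) {
    stop("filter bank and spectrogram disagree on the number of bins")
  }
  nK <- nrow(filt)
  if (nCeps >= nK) stop("nCeps must be smaller than the number of filters")
  E <- log(pmax(filt %*% V, 1e-10))            # K x T log filter-bank outputs
  D <- .dctMatrix(nK)
  C <- D %*% E                                 # DCT along the filter axis
  logE <- log(pmax(colSums(V^2), 1e-10))
  X <- cbind(t(C[2:(nCeps + 1), , drop = FALSE]), logE)
  layout <- c(paste0("c", seq_len(nCeps)), "logE")
  colnames(X) <- layout
  rownames(X) <- NULL
  methods::new("ShortTimeFeatures", X = X, layout = layout)
}

#' Learn per-class spectral basis vectors (SBV model)
#'
#' For each class i, concatenates its training spectrograms into V_i and
#' factorizes it with [nmfDecompose()] at K basis vectors; the per-class
#' bases W_i are column-concatenated into a single matrix W_bs
#' (F x K*C). Columns (i-1)*K+1 .. i*K belong to class i.
#'
#' @param specsByClass named list: class name -> list of
#'   \linkS4class{Spectrogram} objects.
#' @param K basis vectors per class (default 4).
#' @param maxFrames per-class cap on training frames (seeded subsample).
#' @param nRestarts,maxIter,tol,seed passed to [nmfDecompose()]; each
#'   class uses a distinct seed stream derived from \code{seed}.
#' @return an \linkS4class{SbvModel}.
#' @export
learnClassSbvs <- function(specsByClass, K = 4, maxFrames = 4000,
                           nRestarts = 10, maxIter = 200, tol = 1e-6,
                           seed = 1) {
  if (is.null(names(specsByClass)) || any(names(specsByClass) == "")) {
    stop("specsByClass must be a named list (class name -> spectrograms)")
  }
  blocks <- vector("list", length(specsByClass))
  for (i in seq_along(specsByClass)) {
    cls <- names(specsByClass)[i]
    specs <- specsByClass[[i]]
    if (length(specs) == 0) stop("class '", cls, "' has no spectrograms")
    V <- do.call(cbind, lapply(specs, .asMagnitude))
    if (ncol(V) == 0 || sum(V) == 0) {
      stop("class '", cls, "' has no frames with energy")
    }
    if (ncol(V) > maxFrames) {
      keep <- withr::with_seed(.childSeed(seed, "sub", i),
                               sort(sample.int(ncol(V), maxFrames)))
      V <- V[, keep, drop = FALSE]
    }
    fit <- nmfDecompose(V, K, nRestarts = nRestarts, maxIter = maxIter,
                        tol = tol, seed = .childSeed(seed, "class", i))
    blocks[[i]] <- basisMatrix(fit)
  }
  methods::new("SbvModel", Wbs = do.call(cbind, blocks),
               classLabels = names(specsByClass), KPerClass = as.integer(K))
}

#' Activation-derived short-time features (H_CC + G_NMF)
#'
#' Infers activations H_bs of the spectrogram against the fixed
#' concatenated SBV matrix W_bs ([inferActivations()] updates H only),
#' takes H_Log = log(H_bs + floor), decorrelates each frame's K*C H_Log
#' values with the orthonormal DCT-II keeping C1..C\code{nCeps}, and, when
#' \code{withGnmf}, appends the per-frame maximum-gain term
#' \deqn{G\_NMF_t = \arg\max_k H_{bs}[k, t], \quad k \in 1..KC}
#' as a 1-based index (ties resolved to the first index).
#'
#' @param spec a \linkS4class{Spectrogram}.
#' @param model an \linkS4class{SbvModel} with matching bins.
#' @param nCeps number of cepstral-like coefficients kept (default 13).
#' @param withGnmf append the G_NMF column (default TRUE), giving
#'   D = nCeps + 1.
#' @param maxIter,tol,seed passed to [inferActivations()].
#' @return a \linkS4class{ShortTimeFeatures}, layout
#'   \code{hcc1..hcc<nCeps>[, gnmf]}.
#' @export
hccFeatures <- function(spec, model, nCeps = 13, withGnmf = TRUE,
                        maxIter = 200, tol = 1e-6, seed = 1) {
  stopifnot(methods::is(spec, "Spectrogram"), methods::is(model, "SbvModel"))
  Wbs <- model@Wbs
  if (nrow(Wbs) != nrow(spec@mag)) {
    stop("SBV model and spectrogram disagree on the number of bins")
  }
  KC <- ncol(Wbs)
  if (nCeps >= KC) stop("nCeps must be smaller than K * C")
  H <- inferActivations(spec, Wbs, maxIter = maxIter, tol = tol, seed = seed)
  .hccFromH(H, nCeps, withGnmf)
}

# Shared back half of the H_CC extraction: H_Log, DCT, G_NMF.
.hccFromH <- function(H, nCeps, withGnmf) {
  KC <- nrow(H)
  HLog <- log(H + 1e-10)
  C <- .dctMatrix(KC) %*% HLog
  X <- t(C[2:(nCeps + 1), , drop = FALSE])
  layout <- paste0("hcc", seq_len(nCeps))
  if (withGnmf) {
    zero <- colSums(H) == 0
    if (any(zero)) {
      message(sprintf("hccFeatures: %d all-zero activation frames; G_NMF = 1 by first-index tie-break",
                      sum(zero)))
    }
    gnmf <- max.col(t(H), ties.method = "first")   # argmax_k H[k, t]
    X <- cbind(X, as.numeric(gnmf))
    layout <- c(layout, "gnmf")
  }
  colnames(X) <- layout
  rownames(X) <- NULL
  methods::new("ShortTimeFeatures", X = X, layout = layout)
}

# Batched H_CC extraction: the H update is column-separable, so the
# activations of many spectrograms can be inferred in one call on their
# concatenation and split back per recording. Used by the evaluation
# harness; equivalent to per-recording inference up to the random start.
.hccFeaturesBatch <- function(specs, model, nCeps = 13, withGnmf = TRUE,
                              maxIter = 200, tol = 1e-6, seed = 1) {
  Wbs <- model@Wbs
  widths <- vapply(specs, function(s) ncol(.asMagnitude(s)), integer(1))
  V <- do.call(cbind, lapply(specs, .asMagnitude))
  H <- inferActivations(V, Wbs, maxIter = maxIter, tol = tol, seed = seed,
                        traceEvery = 5)
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_along(specs), function(i) {
    .hccFromH(H[, starts[i]:ends[i], drop = FALSE], nCeps, withGnmf)
  })
}

#' Append first-derivative (delta) features
#'
#' Computes per-column delta features by least-squares regression over
#' +/- \code{window} frames with edge replication,
#' \deqn{d_t = \frac{\sum_{n=1}^{w} n (x_{t+n} - x_{t-n})}{2 \sum_{n=1}^{w} n^2}}
#' and appends them, doubling the feature dimension.
#'
#' @param feats a \linkS4class{ShortTimeFeatures}.
#' @param window regression half-width in frames (default 2).
#' @return a \linkS4class{ShortTimeFeatures} with layout
#'   \code{..., d_<name>, ...}.
#' @export
appendDeltas <- function(feats, window = 2) {
  stopifnot(methods::is(feats, "ShortTimeFeatures"))
  X <- feats@X
  nT <- nrow(X)
  denom <- 2 * sum(seq_len(window)^2)
  idx <- function(i) pmin(pmax(i, 1L), nT)     # edge replication
  D <- matrix(0, nT, ncol(X))
  for (n in seq_len(window)) {
    D <- D + n * (X[idx(seq_len(nT) + n), , drop = FALSE] -
                  X[idx(seq_len(nT) - n), , drop = FALSE])
  }
  D <- D / denom
  layout <- c(feats@layout, paste0("d_", feats@layout))
  out <- cbind(X, D)
  colnames(out) <- layout
  methods::new("ShortTimeFeatures", X = out, layout = layout)
}

#' Concatenate two short-time feature sets frame-wise
#'
#' Column-binds two feature matrices over the same frames (e.g. NMF_CC
#' with H_CC + G_NMF); the first set's columns precede the second's.
#'
#' @param a,b \linkS4class{ShortTimeFeatures} with equal frame counts.
#' @return a combined \linkS4class{ShortTimeFeatures}.
#' @export
concatFeatures <- function(a, b) {
  stopifnot(methods::is(a, "ShortTimeFeatures"),
            methods::is(b, "ShortTimeFeatures"))
  if (ncol(b@X) == 0) return(a)
  if (ncol(a@X) == 0) return(b)
  if (nrow(a@X) != nrow(b@X)) {
    stop(sprintf("frame counts differ: %d vs %d", nrow(a@X), nrow(b@X)))
  }
  layout <- c(a@layout, b@layout)
  X <- cbind(a@X, b@X)
  colnames(X) <- layout
  methods::new("ShortTimeFeatures", X = X, layout = layout)
}
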