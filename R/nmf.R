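#' Generalized Kullback-Leibler divergence D(V || WH)
#'
#' \deqn{D_{KL}(V \| WH) = \sum_{ij} V_{ij} \log\frac{V_{ij}}{(WH)_{ij}}
#'   - V_{ij} + (WH)_{ij}}
#' with the convention \eqn{0 \log(0/x) = 0}. This is the cost minimized
#' by the multiplicative NMF updates. When \eqn{(WH)_{ij} = 0} at a
#' position where \eqn{V_{ij} > 0} the divergence is \code{Inf} (returned,
#' not an error).
#'
#' @param V non-negative matrix (or \linkS4class{Spectrogram}).
#' @param W,H non-negative factor matrices with conformable shapes.
#' @return a non-negative scalar (possibly \code{Inf}).
#' @export
klDivergence <- function(V, W, H) {
  V <- .asMagnitude(V)
  .checkNonneg(V, "V"); .checkNonneg(W, "W"); .checkNonneg(H, "H")
  WH <- W %*% H
  if (any(WH == 0 & V > 0)) return(Inf)
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

#' Multiplicative KL update of the basis matrix W
#'
#' One Lee-Seung multiplicative step
#' \deqn{W \leftarrow W \otimes \frac{(V \oslash WH) H^T}{\mathbf{1} H^T}}
#' (element-wise multiply/divide). Non-negativity is preserved and the KL
#' divergence does not increase. Denominators and the quotient are floored
#' at 1e-12 to avoid 0/0.
#'
#' @param V non-negative data matrix (F x T).
#' @param W non-negative basis matrix (F x K).
#' @param H non-negative activation matrix (K x T).
#' @return the updated W.
#' @export
updateW <- function(V, W, H) {
  V <- .asMagnitude(V)
  WH <- pmax(W %*% H, .EPS)
  num <- (V / WH) %*% t(H)
  W * sweep(num, 2, pmax(rowSums(H), .EPS), "/")
}

#' Multiplicative KL update of the activation matrix H
#'
#' Mirror image of [updateW()]:
#' \deqn{H \leftarrow H \otimes \frac{W^T (V \oslash WH)}{W^T \mathbf{1}}}
#'
#' @inheritParams updateW
#' @return the updated H.
#' @export
updateH <- function(V, W, H) {
  V <- .asMagnitude(V)
  WH <- pmax(W %*% H, .EPS)
  num <- crossprod(W, V / WH)
  H * sweep(num, 1, pmax(colSums(W), .EPS), "/")
}

# Scale-matched random non-negative init: entries in (0, 1] scaled so that
# E[(WH)_ij] matches mean(V).
.randomInit <- function(nF, nT, K, scaleV) {
  s <- sqrt(4 * max(scaleV, .EPS) / K)
  list(W = matrix((1 - stats::runif(nF * K)) * s, nF, K),
       H = matrix((1 - stats::runif(K * nT)) * s, K, nT))
}

#' KL-NMF decomposition with multi-restart initialization
#'
#' Factorizes a non-negative matrix V (F x T) as W H (F x K times K x T)
#' by alternating the multiplicative updates of [updateW()] and
#' [updateH()]. Initialization follows the multi-restart protocol: draw
#' \code{nRestarts} random non-negative (W, H) pairs, keep the pair with
#' the smallest Euclidean (Frobenius) distance to V, then refine it by
#' minimizing the KL divergence for up to \code{maxIter} update sweeps,
#' stopping early when the relative KL change falls below \code{tol}.
#'
#' @param V non-negative matrix or \linkS4class{Spectrogram}.
#' @param K number of basis vectors; a warning is issued when
#'   K > min(F, T).
#' @param nRestarts number of random initial candidates (default 10).
#' @param maxIter maximum number of update sweeps (default 200).
#' @param tol relative KL-change early-stopping tolerance (default 1e-6).
#' @param seed integer seed; the run is fully deterministic given it.
#' @return an \linkS4class{NMFModel}.
#' @export
nmfDecompose <- function(V, K, nRestarts = 10, maxIter = 200, tol = 1e-6,
                         seed = 1) {
  V <- .asMagnitude(V)
  .checkNonneg(V, "V")
  if (K < 1) stop("K must be >= 1")
  if (K > min(dim(V))) {
    warning(sprintf("K = %d exceeds min(F, T) = %d; the factorization is overcomplete",
                    K, min(dim(V))))
  }
  mV <- mean(V)
  best <- NULL
  bestDist <- Inf
  for (r in seq_len(nRestarts)) {
    cand <- withr::with_seed(.childSeed(seed, "init", r),
                             .randomInit(nrow(V), ncol(V), K, mV))
    d <- sqrt(sum((V - cand$W %*% cand$H)^2))
    if (d < bestDist) { bestDist <- d; best <- cand }
  }
  fit <- .cppNmfDecomposeLoop(V, best$W, best$H, as.integer(maxIter), tol)
  methods::new("NMFModel", W = fit$W, H = fit$H,
               divergenceTrace = as.numeric(fit$trace),
               config = list(K = K, nRestarts = nRestarts, maxIter = maxIter,
                             tol = tol, seed = seed,
                             iterations = length(trace)))
}

#' Infer activations against a fixed spectral basis
#'
#' Given a fixed basis \code{W} (e.g. the concatenated per-species SBV
#' matrix), factorizes V by updating only the activation matrix H with
#' [updateH()], from a seeded random start. The KL divergence is
#' non-increasing over iterations.
#'
#' @param V non-negative matrix or \linkS4class{Spectrogram} with F rows.
#' @param W fixed non-negative basis matrix (F x K).
#' @param maxIter maximum update iterations (default 200).
#' @param tol relative KL-change early-stopping tolerance (default 1e-6).
#' @param seed integer seed for the random H start.
#' @param traceEvery evaluate the KL divergence (for the trace and the
#'   stopping rule) every this many iterations (default 1; the final
#'   iteration is always evaluated). The updates themselves are
#'   unaffected.
#' @return the inferred K x T activation matrix, with the recorded KL
#'   values in \code{attr(, "divergenceTrace")}.
#' @export
inferActivations <- function(V, W, maxIter = 200, tol = 1e-6, seed = 1,
                             traceEvery = 1) {
  V <- .asMagnitude(V)
  .checkNonneg(V, "V"); .checkNonneg(W, "W")
  if (nrow(W) != nrow(V)) stop("W must have as many rows as V")
  zeroRows <- rowSums(W) == 0 & rowSums(V) > 0
  if (any(zeroRows)) {
    message(sprintf(
      "inferActivations: %d all-zero basis rows face positive data; divergence is unbounded there",
      sum(zeroRows)))
  }
  K <- ncol(W)
  sH <- mean(V) / max(mean(W) * K, .EPS)
  H <- withr::with_seed(.childSeed(seed, "acts"),
                        matrix((1 - stats::runif(K * ncol(V))) * 2 * sH,
                               K, ncol(V)))
  fit <- .cppNmfInferLoop(V, W, H, as.integer(maxIter), tol,
                          as.integer(traceEvery))
  H <- fit$H
  attr(H, "divergenceTrace") <- as.numeric(fit$trace)
  H
}
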