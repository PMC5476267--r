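# Internal numerical helpers.

# Epsilon floor used inside every division and log of the NMF updates.
.EPS <- 1e-12

# Derive a child seed below 2^31 from a master seed and a stream label.
# Deterministic, cheap, and keeps independent stages on separate streams.
.childSeed <- function(seed, ...) {
  parts <- c(seed, vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else
      as.numeric(p)
  }, numeric(1)))
  s <- 0
  for (p in parts) s <- (s * 69069 + (as.numeric(p) %% 2147483647)) %% 2147483647
  as.integer(s %% 2147483629 + 1)
}

#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the square linear assignment problem: given an n x n cost matrix,
#' find the permutation \code{p} minimizing \code{sum(cost[i, p[i]])}.
#' Used to match learned NMF basis vectors to planted dictionary atoms.
#'
#' @param cost numeric n x n matrix of finite costs.
#' @return integer vector \code{p} of length n; row i is assigned column
#'   \code{p[i]}.
#' @examples
#' hungarianAssignment(matrix(c(4, 2, 1, 3), 2, 2))
#' @export
hungarianAssignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  # Jonker-style shortest augmenting path, O(n^3); 1-based with 0 sentinel.
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)      # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L               # column index + 1 offset: slot 1 is the virtual col
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  out <- integer(n)
  for (j in seq_len(n)) out[p[j + 1L]] <- j
  out
}

# Mean best-match cosine similarity between the columns of two matrices,
# under the optimal one-to-one assignment (scale/permutation-invariant
# dictionary recovery score).
.matchedCosine <- function(West, Wtrue) {
  nc <- function(M) sweep(M, 2, pmax(sqrt(colSums(M^2)), .EPS), "/")
  A <- nc(West); B <- nc(Wtrue)
  sim <- crossprod(A, B)            # K x K cosine similarities
  perm <- hungarianAssignment(1 - sim)
  mean(sim[cbind(seq_len(ncol(A)), perm)])
}

# Stop unless x is a non-negative numeric matrix.
.checkNonneg <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  }
  if (any(x < 0)) stop(sprintf("'%s' must be non-negative", name),
                       call. = FALSE)
  invisible(TRUE)
}

# Coerce Spectrogram or matrix input to the plain magnitude matrix.
.asMagnitude <- function(V) {
  if (methods::is(V, "Spectrogram")) V@mag else V
}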