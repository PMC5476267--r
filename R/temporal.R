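#' Moment skewness
#'
#' Population moment skewness \eqn{g_1 = m_3 / m_2^{3/2}} with central
#' moments \eqn{m_k = \frac{1}{N}\sum (x_i - \bar x)^k}; defined as 0 when
#' \eqn{m_2 = 0} (constant sequences).
#'
#' @param x numeric vector, length >= 1.
#' @return a single numeric value.
#' @examples
#' momentSkewness(c(1, 2, 3))   # 0 (symmetric)
#' momentSkewness(c(1, 1, 4))   # ~0.7071
#' @export
momentSkewness <- function(x) {
  if (length(x) < 1) stop("x must have length >= 1")
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 <= 0) return(0)
  mean(d^3) / m2^1.5
}

#' Collapse a syllable's frames into one segmental feature vector
#'
#' Temporal feature integration: for each short-time feature column, the
#' mean, population standard deviation and moment skewness are computed
#' over the frames of the segment \code{[startFrame, endFrame)} (0-based,
#' half-open), and concatenated statistic-major: all means, then all
#' standard deviations, then all skewnesses (3 x D values).
#'
#' @param feats a \linkS4class{ShortTimeFeatures}.
#' @param startFrame,endFrame segment bounds, 0-based half-open.
#' @return named numeric vector of length 3 * D
#'   (\code{mean_*, sd_*, skew_*}).
#' @export
integrateSegment <- function(feats, startFrame, endFrame) {
  stopifnot(methods::is(feats, "ShortTimeFeatures"))
  nT <- nrow(feats@X)
  if (startFrame < 0 || endFrame > nT || startFrame >= endFrame) {
    stop(sprintf("segment [%d, %d) out of range for %d frames",
                 startFrame, endFrame, nT))
  }
  X <- feats@X[(startFrame + 1):endFrame, , drop = FALSE]
  mu <- colMeans(X)
  d <- sweep(X, 2, mu)
  m2 <- colMeans(d^2)
  sdv <- sqrt(m2)
  skw <- ifelse(m2 > 0, colMeans(d^3) / pmax(m2, .EPS)^1.5, 0)
  out <- c(mu, sdv, skw)
  names(out) <- c(paste0("mean_", feats@layout), paste0("sd_", feats@layout),
                  paste0("skew_", feats@layout))
  out
}

#' Segmental features for every syllable of a recording
#'
#' Applies [integrateSegment()] to each row of a syllable segment table.
#'
#' @param feats a \linkS4class{ShortTimeFeatures}.
#' @param segments data.frame with \code{startFrame}/\code{endFrame}
#'   columns as returned by [segmentSyllables()].
#' @return matrix with one row per syllable (0 rows when no segments) and
#'   3 * D named columns.
#' @export
integrateSyllables <- function(feats, segments) {
  nD <- 3L * ncol(feats@X)
  if (nrow(segments) == 0) {
    out <- matrix(numeric(0), 0, nD)
    colnames(out) <- c(paste0("mean_", feats@layout),
                       paste0("sd_", feats@layout),
                       paste0("skew_", feats@layout))
    return(out)
  }
  t(vapply(seq_len(nrow(segments)), function(i) {
    integrateSegment(feats, segments$startFrame[i], segments$endFrame[i])
  }, numeric(nD)))
}
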