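#' Manders M1 colocalization coefficient
#'
#' Fraction of the reference channel's total intensity that lies inside the
#' signal mask of a second channel: \code{M1 = sum(ref[mask]) / sum(ref)}.
#' This is the "proportion of total fluorescence overlapping the second
#' channel" reading of the Manders overlap analysis and is the default
#' colocalization value reported by the package.
#'
#' @param refChannel numeric matrix, reference intensities.
#' @param otherMask logical/0-1 matrix, signal mask of the second channel
#'   (e.g. Otsu foreground); same shape as \code{refChannel}.
#' @return value in [0, 1]; 0 when the reference channel sums to 0.
#' @examples
#' r <- matrix(1:4, 1); m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 1)
#' mandersM1(r, m)  # 3/10
#' @export
mandersM1 <- function(refChannel, otherMask) {
  if (!identical(dim(refChannel), dim(otherMask)))
    stop("reference channel and mask shapes differ")
  tot <- sum(refChannel)
  if (tot == 0) return(0)
  sum(refChannel[otherMask != 0]) / tot
}

#' Intensity-weighted overlap coefficient
#'
#' \code{sum(R * G) / sqrt(sum(R^2) * sum(G^2))}: the overlap variant that
#' weights pixels by intensity in both channels. Invariant under positive
#' rescaling of either channel; 1 for identical channels, 0 for disjoint
#' supports.
#'
#' @param refChannel,otherChannel co-registered numeric matrices.
#' @return value in [0, 1].
#' @export
overlapCoefficient <- function(refChannel, otherChannel) {
  if (!identical(dim(refChannel), dim(otherChannel)))
    stop("channel shapes differ")
  s1 <- sum(refChannel^2); s2 <- sum(otherChannel^2)
  if (s1 == 0 && s2 == 0) stop("both channels are all zero")
  if (s1 == 0 || s2 == 0) return(0)
  sum(refChannel * otherChannel) / sqrt(s1 * s2)
}

#' Per-cell colocalization of two channels of a CellImage
#'
#' Convenience wrapper: projects the image, subtracts each channel's
#' background (mean of its below-Otsu pixels, clamped at zero) so that
#' camera noise does not dilute the coefficients, builds the Otsu mask of
#' the second channel, and returns both Manders M1 and the
#' intensity-weighted overlap coefficient.
#'
#' @param image a [CellImage-class].
#' @param refRole,otherRole channel roles (reference and masking channel).
#' @param backgroundSubtract subtract the below-threshold mean first,
#'   default TRUE.
#' @return named numeric: \code{m1}, \code{overlap}.
#' @export
colocalize <- function(image, refRole, otherRole,
                       backgroundSubtract = TRUE) {
  img <- maxProjection(image)
  ref <- getChannel(img, refRole)
  oth <- getChannel(img, otherRole)
  maxv <- 2^image@bitDepth - 1
  mask <- oth > otsuThreshold(oth, maxValue = maxv)
  if (backgroundSubtract) {
    # robust background: mean + 2 SD of the dimmest 80% of pixels (signal
    # occupies a small pixel fraction), so clamped camera noise does not
    # accumulate in the denominators
    sub <- function(ch) {
      lo <- ch[ch <= quantile(ch, 0.8)]
      bg <- mean(lo) + 2 * sd(lo)
      if (!is.finite(bg)) bg <- 0
      pmax(ch - bg, 0)
    }
    ref <- sub(ref); oth <- sub(oth)
  }
  c(m1 = mandersM1(ref, mask), overlap = overlapCoefficient(ref, oth))
}
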