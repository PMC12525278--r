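#' Golgi morphology metrics
#'
#' Quantifies Golgi dispersion for one cell from binary masks:
#' \itemize{
#'   \item \strong{nucleus distance}: the Golgi pixel farthest from the
#'     nucleus centroid is located, and the reported distance is from that
#'     extremity to the nearest nucleus pixel, in micrometres;
#'   \item \strong{fragment count}: connected components of the Golgi mask
#'     (connectivity configurable, default 4);
#'   \item \strong{classification}: \code{"fragmented_or_beehive"} when the
#'     fragment count exceeds \code{fragmentMax} or the nucleus distance
#'     exceeds \code{distanceFactor} times the nucleus equivalent radius,
#'     otherwise \code{"unfragmented"}. The published work reports the class
#'     prevalence without an operational rule; this rule is the package's
#'     calibrated default and both thresholds are configurable.
#' }
#'
#' @param golgiMask,nucleusMask logical/0-1 matrices, same shape, both
#'   non-empty.
#' @param pixelSizeNM lateral pixel size in nanometres.
#' @param connectivity component connectivity for the fragment count.
#' @param fragmentMax fragment-count bound of the classifier, default 5.
#' @param distanceFactor nucleus-radius multiple of the classifier,
#'   default 2.
#' @return a \code{GolgiMorphology} list: \code{classification},
#'   \code{fragmentCount}, \code{nucleusDistanceUM},
#'   \code{nucleusRadiusUM}.
#' @examples
#' nuc <- matrix(FALSE, 64, 64); nuc[20:40, 20:40] <- TRUE
#' gol <- matrix(FALSE, 64, 64); gol[50, 55] <- TRUE
#' golgiMetrics(gol, nuc, pixelSizeNM = 100)
#' @export
golgiMetrics <- function(golgiMask, nucleusMask, pixelSizeNM,
                         connectivity = 4L, fragmentMax = 5L,
                         distanceFactor = 2) {
  if (!any(nucleusMask != 0)) stop("empty nucleus mask")
  if (!any(golgiMask != 0)) stop("empty Golgi mask")
  if (!identical(dim(golgiMask), dim(nucleusMask)))
    stop("mask shapes differ")
  nucPx <- which(nucleusMask != 0, arr.ind = TRUE)
  golPx <- which(golgiMask != 0, arr.ind = TRUE)
  ctr <- colMeans(nucPx)
  dc <- sqrt((golPx[, 1L] - ctr[1L])^2 + (golPx[, 2L] - ctr[2L])^2)
  far <- golPx[which.max(dc), ]
  dn <- sqrt((nucPx[, 1L] - far[1L])^2 + (nucPx[, 2L] - far[2L])^2)
  distUM <- min(dn) * pixelSizeNM / 1000
  fragments <- max(labelComponents(golgiMask != 0, connectivity))
  eqRadUM <- sqrt(nrow(nucPx) / pi) * pixelSizeNM / 1000
  cls <- if (fragments > fragmentMax || distUM > distanceFactor * eqRadUM)
    "fragmented_or_beehive" else "unfragmented"
  structure(list(classification = cls, fragmentCount = as.integer(fragments),
                 nucleusDistanceUM = distUM, nucleusRadiusUM = eqRadUM),
            class = "GolgiMorphology")
}

#' @export
print.GolgiMorphology <- function(x, ...) {
  cat(sprintf("Golgi: %s (%d fragment(s), nucleus distance %.2f um)\n",
              x$classification, x$fragmentCount, x$nucleusDistanceUM))
  invisible(x)
}
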