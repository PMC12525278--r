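#' Peak-to-peak distance of an intensity profile
#'
#' The lysosome diameter definition used throughout: on a line profile
#' crossing a membrane-stained (rim-bright) organelle, the diameter is the
#' distance between the two outermost local intensity maxima. The profile is
#' smoothed with a short moving mean, peaks must exceed a prominence
#' fraction of the profile range, and peak positions are refined to
#' sub-sample precision by parabolic interpolation. Profiles showing a
#' single unresolved peak return its full width at half maximum instead,
#' flagged as such.
#'
#' @param values numeric profile samples.
#' @param spacingNM sample spacing in nanometres.
#' @param smooth moving-mean window (samples), default 3.
#' @param prominenceFrac required peak prominence as a fraction of the
#'   profile range, default 0.1.
#' @return list: \code{diameterNM}, \code{nPeaks}, \code{method}
#'   (\code{"peak_distance"} or \code{"fwhm"}), \code{unresolved} flag.
#' @examples
#' profilePeakDistance(c(0, 1, 5, 1, 0, 1, 5, 1, 0), spacingNM = 100)
#' @export
profilePeakDistance <- function(values, spacingNM, smooth = 3L,
                                prominenceFrac = 0.1) {
  n <- length(values)
  if (n < 3L) stop("profile has fewer than 3 samples")
  v <- values
  if (smooth > 1L) {
    sm <- as.numeric(stats::filter(values, rep(1 / smooth, smooth),
                                   sides = 2L))
    v <- ifelse(is.na(sm), values, sm)
  }
  rng <- diff(range(values))
  peaks <- which(diff(sign(diff(v))) < 0) + 1L       # interior local maxima
  if (rng > 0 && length(peaks)) {
    prom <- vapply(peaks, function(i) .peakProminence(v, i), numeric(1))
    peaks <- peaks[prom >= prominenceFrac * rng]
  }
  refine <- function(i) {
    if (i <= 1L || i >= n) return(i - 1)
    den <- v[i - 1L] - 2 * v[i] + v[i + 1L]
    off <- if (den == 0) 0 else 0.5 * (v[i - 1L] - v[i + 1L]) / den
    (i - 1) + max(min(off, 0.5), -0.5)
  }
  if (length(peaks) >= 2L) {
    p1 <- refine(min(peaks)); p2 <- refine(max(peaks))
    return(list(diameterNM = (p2 - p1) * spacingNM,
                nPeaks = length(peaks), method = "peak_distance",
                unresolved = FALSE))
  }
  # unresolved object: full width at half maximum of the single peak
  pk <- if (length(peaks)) peaks else which.max(v)
  half <- (max(v) + min(v)) / 2
  above <- which(v >= half)
  list(diameterNM = (max(above) - min(above)) * spacingNM,
       nPeaks = length(peaks), method = "fwhm", unresolved = TRUE)
}

# topographic prominence of a local maximum within a 1-D profile
.peakProminence <- function(v, i) {
  left <- v[seq_len(i - 1L)]; right <- v[seq(i + 1L, length(v))]
  sideMin <- function(side) {
    higher <- which(side > v[i])
    if (length(higher) == 0L) min(side)
    else if (identical(side, left)) min(side[seq(max(higher), length(side))])
    else min(side[seq_len(min(higher))])
  }
  lo <- max(if (i > 1L) sideMin(left) else -Inf,
            if (i < length(v)) sideMin(right) else -Inf)
  v[i] - lo
}

#' Lysosome diameter from an intensity profile through the object
#'
#' For one labeled object of the lysosome-membrane channel: samples an
#' intensity profile through the object centroid along its major axis
#' (extended a few pixels past the object) and applies the peak-distance
#' rule of [profilePeakDistance()].
#'
#' @param image a [CellImage-class] with the membrane channel.
#' @param labelMask integer label matrix (e.g. from [segmentChannel()]).
#' @param label object label to measure.
#' @param role channel role, default \code{"LAMP1"}.
#' @param marginPx profile extension beyond the object extent, default 3.
#' @param ... passed to [profilePeakDistance()].
#' @return list as [profilePeakDistance()], plus \code{label}.
#' @export
lysosomeDiameter <- function(image, labelMask, label, role = "LAMP1",
                             marginPx = 3, ...) {
  px <- which(labelMask == label, arr.ind = TRUE)
  if (nrow(px) < 3L) stop("object ", label, " smaller than 3 profile samples")
  ctr <- colMeans(px)                     # 1-based (row, col)
  xy <- sweep(px, 2L, ctr)
  cv <- crossprod(xy) / nrow(px)
  dir <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
  ext <- max(abs(xy %*% dir)) + marginPx
  d <- dim(labelMask)
  clip <- function(p) pmin(pmax(p, 0), d - 1)
  p0 <- clip(ctr - 1 + ext * dir)         # 0-based endpoints
  p1 <- clip(ctr - 1 - ext * dir)
  prof <- lineProfile(image, role, p0, p1)
  res <- profilePeakDistance(prof$values, prof$spacingNM, ...)
  res$label <- label
  res
}

#' Measure all lysosome diameters in an image
#'
#' Segments the membrane channel and measures each object with
#' [lysosomeDiameter()], skipping objects too small to profile.
#'
#' @param image a [CellImage-class].
#' @param role membrane channel role, default \code{"LAMP1"}.
#' @param minObjectPx passed to [segmentChannel()] (default 12: discards
#'   sub-resolution specks).
#' @param keepUnresolved keep FWHM-flagged single-peak objects (default
#'   FALSE, matching the peak-distance definition).
#' @param ... passed to [lysosomeDiameter()].
#' @return data.frame: \code{label}, \code{diameterNM}, \code{method},
#'   \code{unresolved}.
#' @export
measureLysosomes <- function(image, role = "LAMP1", minObjectPx = 12L,
                             keepUnresolved = FALSE, ...) {
  lab <- segmentChannel(image, role, minObjectPx = minObjectPx)
  k <- max(lab)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    r <- tryCatch(lysosomeDiameter(image, lab, i, role = role, ...),
                  error = function(e) NULL)
    if (!is.null(r))
      out[[i]] <- data.frame(label = i, diameterNM = r$diameterNM,
                             method = r$method, unresolved = r$unresolved)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(data.frame(label = integer(), diameterNM = numeric(),
                                      method = character(), unresolved = logical()))
  if (!keepUnresolved) res <- res[!res$unresolved, , drop = FALSE]
  res
}

#' Lysosomal network porosity on a fixed tile grid
#'
#' The lysosomal network region is the morphological closure of the
#' lysosome mask (filling the gaps between neighbouring lysosomes). Square
#' tiles (default 50 x 50 px) are laid on a regular grid anchored at the
#' region bounding-box origin; every tile lying entirely inside the region
#' contributes a porosity value: the percentage of its pixels that are
#' "pores", i.e. region pixels not covered by lysosome signal. Tiles
#' straddling the region boundary are dropped, not padded. Dispersed
#' networks score higher porosity than clustered ones.
#'
#' @param lysosomeMask logical/0-1 matrix of lysosome signal.
#' @param networkRegion optional logical matrix defining the network region;
#'   computed as the closure of \code{lysosomeMask} when \code{NULL}.
#' @param tilePx tile edge in pixels, default 50.
#' @param closeRadiusPx disc radius of the closing used to build the region,
#'   default 25.
#' @return numeric vector of per-tile porosities (percent, in [0, 100]).
#' @export
networkPorosity <- function(lysosomeMask, networkRegion = NULL, tilePx = 50L,
                            closeRadiusPx = 25L) {
  m <- lysosomeMask != 0
  if (is.null(networkRegion)) {
    if (!any(m)) stop("empty lysosome mask: no network region")
    brush <- EBImage::makeBrush(2L * closeRadiusPx + 1L, shape = "disc")
    networkRegion <- EBImage::closing(matrix(as.numeric(m), nrow(m)), brush) > 0
  }
  reg <- networkRegion != 0
  rr <- range(which(rowSums(reg) > 0)); cc <- range(which(colSums(reg) > 0))
  if (diff(rr) + 1L < tilePx || diff(cc) + 1L < tilePx)
    stop("network region smaller than one ", tilePx, "x", tilePx,
         " px tile; use a smaller tile or a larger field")
  poros <- numeric(0)
  for (r0 in seq(rr[1L], rr[2L] - tilePx + 1L, by = tilePx)) {
    for (c0 in seq(cc[1L], cc[2L] - tilePx + 1L, by = tilePx)) {
      tileReg <- reg[r0:(r0 + tilePx - 1L), c0:(c0 + tilePx - 1L)]
      if (!all(tileReg)) next                      # tile straddles boundary
      tileLys <- m[r0:(r0 + tilePx - 1L), c0:(c0 + tilePx - 1L)]
      poros <- c(poros, 100 * sum(!tileLys) / (tilePx * tilePx))
    }
  }
  poros
}
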