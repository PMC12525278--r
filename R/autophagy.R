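#' p62 aggregate density per cell area
#'
#' Counts thresholded p62 puncta within a cell mask and divides by the cell
#' area in square micrometres. An aggregate is a connected component of
#' above-threshold pixels inside the cell whose area lies within configured
#' physical bounds (defaults 0.05-5 um^2, excluding single-pixel noise and
#' large diffuse patches).
#'
#' @param p62Channel numeric matrix of p62 intensities.
#' @param cellMask logical/0-1 matrix delimiting the cell; must be
#'   non-empty.
#' @param pixelSizeNM lateral pixel size in nanometres.
#' @param minAreaUM2,maxAreaUM2 aggregate area bounds in um^2.
#' @param threshold raw-scale intensity threshold; Otsu when \code{NULL}.
#' @param maxValue intensity range top for Otsu, default 255.
#' @return list: \code{densityPerUM2}, \code{count}, \code{cellAreaUM2}.
#' @export
p62AggregateDensity <- function(p62Channel, cellMask, pixelSizeNM,
                                minAreaUM2 = 0.05, maxAreaUM2 = 5,
                                threshold = NULL, maxValue = 255) {
  if (!any(cellMask != 0)) stop("empty cell mask")
  pxAreaUM2 <- (pixelSizeNM / 1000)^2
  cellAreaUM2 <- sum(cellMask != 0) * pxAreaUM2
  inCell <- p62Channel * (cellMask != 0)
  thr <- if (is.null(threshold)) otsuThreshold(inCell, maxValue) else threshold
  mask <- inCell > thr
  count <- 0L
  if (any(mask)) {
    lab <- labelComponents(mask)
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab)) * pxAreaUM2
    count <- sum(sizes >= minAreaUM2 & sizes <= maxAreaUM2)
  }
  list(densityPerUM2 = count / cellAreaUM2, count = as.integer(count),
       cellAreaUM2 = cellAreaUM2)
}

#' Mean intensity of the segmented signal of one channel
#'
#' Per-cell readout used for the LysoSensor assay: mean raw intensity over
#' the Otsu foreground of the channel (whole image when the channel is
#' empty).
#'
#' @param image a [CellImage-class].
#' @param role channel role, default \code{"LYSOSENSOR"}.
#' @return numeric scalar.
#' @export
cellMeanIntensity <- function(image, role = "LYSOSENSOR") {
  ch <- getChannel(maxProjection(image), role)
  maxv <- 2^image@bitDepth - 1
  thr <- otsuThreshold(ch, maxValue = maxv)
  if (!is.finite(thr) || !any(ch > thr)) return(mean(ch))
  mean(ch[ch > thr])
}

#' LysoSensor relative intensity
#'
#' Normalizes per-cell mean LysoSensor intensities to the control group,
#' replicate by replicate: each cell's value is divided by the mean of the
#' control cells of the same replicate, so the control grand mean is ~1 and
#' patient values are relative units. Lower values indicate a less acidic
#' (higher-pH) lysosomal lumen.
#'
#' @param cells data.frame with columns \code{group}, \code{replicate},
#'   \code{intensity} (one row per cell).
#' @param controlGroup control label, default \code{"CT"}.
#' @return \code{cells} with an added \code{relative} column.
#' @export
lysosensorRelativeIntensity <- function(cells, controlGroup = "CT") {
  if (!controlGroup %in% cells$group)
    stop("control group '", controlGroup, "' absent")
  ctrl <- cells[cells$group == controlGroup, ]
  refs <- tapply(ctrl$intensity, ctrl$replicate, mean)
  if (any(refs == 0)) stop("a control replicate has zero mean intensity")
  reps <- as.character(cells$replicate)
  if (!all(reps %in% names(refs)))
    stop("every replicate needs control cells for normalization")
  cells$relative <- cells$intensity / as.numeric(refs[reps])
  cells
}
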