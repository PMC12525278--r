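#' Label connected foreground components
#'
#' Connected-component labeling of a binary mask with selectable pixel
#' connectivity. Labels are consecutive positive integers; background is 0.
#' Fragment counts depend on the connectivity, so it is exposed everywhere a
#' count is derived (default 4-neighbour).
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer label matrix of the same shape.
#' @export
labelComponents <- function(mask, connectivity = 4L) {
  stopifnot(is.matrix(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)  # 4-connected
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8L && max(lab) > 1L) {
    # merge 4-connected labels that touch diagonally (union-find on labels)
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]   # down-right pairs
    a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]   # down-left pairs
    keep1 <- a1 > 0L & b1 > 0L & a1 != b1
    keep2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                          cbind(a2[keep2], b2[keep2])))
    parent <- seq_len(max(lab))
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_along(parent), find, integer(1))
    remap <- match(root, sort(unique(root)))
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Otsu threshold of a channel
#'
#' Between-class-variance threshold on a 256-bin histogram over the image
#' bit-depth range.
#'
#' @param mat numeric matrix on the raw intensity scale.
#' @param maxValue top of the intensity range (e.g. 255 for 8-bit).
#' @return threshold on the raw scale; pixels strictly above it are
#'   foreground.
#' @export
otsuThreshold <- function(mat, maxValue = 255) {
  if (all(mat == 0)) return(Inf)
  EBImage::otsu(pmin(mat / maxValue, 1), range = c(0, 1), levels = 256L) * maxValue
}

#' Segment one channel into labeled objects
#'
#' Thresholds the (projected) channel, removes objects below a minimum pixel
#' area, and labels the remaining connected components 1..K.
#'
#' @param image a [CellImage-class].
#' @param role channel role to segment.
#' @param method \code{"otsu"} (default) or \code{"fixed"}.
#' @param threshold raw-scale threshold, required for \code{method="fixed"}.
#' @param minObjectPx minimum object area in pixels (default 4).
#' @param connectivity component connectivity, 4 (default) or 8.
#' @return integer label matrix (a label mask); all-zero channels yield an
#'   all-zero mask, not an error.
#' @export
segmentChannel <- function(image, role, method = c("otsu", "fixed"),
                           threshold = NULL, minObjectPx = 4L,
                           connectivity = 4L) {
  method <- match.arg(method)
  ch <- getChannel(maxProjection(image), role)
  maxv <- 2^image@bitDepth - 1
  thr <- switch(method,
    otsu  = otsuThreshold(ch, maxValue = maxv),
    fixed = { if (is.null(threshold)) stop("method='fixed' needs a threshold"); threshold })
  mask <- ch > thr
  if (!any(mask)) return(matrix(0L, nrow(ch), ncol(ch)))
  lab <- labelComponents(mask, connectivity = connectivity)
  if (minObjectPx > 1L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    drop <- which(sizes < minObjectPx)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      keep <- sort(unique(lab[lab > 0L]))
      lab[lab > 0L] <- match(lab[lab > 0L], keep)
    }
  }
  lab
}

#' Sample an intensity profile along a line segment
#'
#' Bilinear interpolation at sub-pixel sample spacing (at most one pixel),
#' with distances converted to nanometres by the image pixel size. Endpoint
#' coordinates are 0-based \code{(row, col)}.
#'
#' @param image a [CellImage-class] (projected internally).
#' @param role channel role to sample.
#' @param p0,p1 numeric length-2 endpoints, 0-based (row, col); must lie
#'   inside the image.
#' @return an \code{IntensityProfile}: list with \code{values},
#'   \code{spacingNM}, \code{lengthNM}.
#' @export
lineProfile <- function(image, role, p0, p1) {
  ch <- getChannel(maxProjection(image), role)
  lenPx <- sqrt(sum((p1 - p0)^2))
  if (lenPx == 0) stop("degenerate segment: p0 equals p1")
  inside <- function(p) all(p >= 0) && p[1L] <= nrow(ch) - 1 && p[2L] <= ncol(ch) - 1
  if (!inside(p0) || !inside(p1)) stop("profile endpoints must lie inside the image")
  n <- ceiling(lenPx) + 1L            # spacing <= 1 px
  t <- seq(0, 1, length.out = n)
  rows <- p0[1L] + t * (p1[1L] - p0[1L])
  cols <- p0[2L] + t * (p1[2L] - p0[2L])
  vals <- bilinearSample(ch, rows, cols)
  spacing <- lenPx / (n - 1L) * image@pixelSizeNM
  structure(list(values = vals, spacingNM = spacing,
                 lengthNM = lenPx * image@pixelSizeNM),
            class = "IntensityProfile")
}

# bilinear interpolation at 0-based fractional (row, col) positions
bilinearSample <- function(mat, rows, cols) {
  r0 <- pmin(floor(rows), nrow(mat) - 2); r0 <- pmax(r0, 0)
  c0 <- pmin(floor(cols), ncol(mat) - 2); c0 <- pmax(c0, 0)
  fr <- rows - r0; fc <- cols - c0
  i00 <- cbind(r0 + 1, c0 + 1); i10 <- cbind(r0 + 2, c0 + 1)
  i01 <- cbind(r0 + 1, c0 + 2); i11 <- cbind(r0 + 2, c0 + 2)
  (1 - fr) * (1 - fc) * mat[i00] + fr * (1 - fc) * mat[i10] +
    (1 - fr) * fc * mat[i01] + fr * fc * mat[i11]
}
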