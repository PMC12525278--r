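#' @rdname channelNames
#' @aliases channelNames,CellImage-method
setMethod("channelNames", "CellImage", function(x) names(x@channels))

#' @rdname getChannel
#' @aliases getChannel,CellImage-method
setMethod("getChannel", "CellImage", function(x, role) {
  if (!role %in% names(x@channels))
    stop("channel role '", role, "' not present; available: ",
         paste(names(x@channels), collapse = ", "))
  x@channels[[role]]
})

#' @rdname zCount
#' @aliases zCount,CellImage-method
setMethod("zCount", "CellImage", function(x) x@zCount)

#' @rdname pixelSize
#' @aliases pixelSize,CellImage-method
setMethod("pixelSize", "CellImage", function(x) x@pixelSizeNM)

setMethod("show", "CellImage", function(object) {
  d <- dim(object@channels[[1L]])
  cat("CellImage:", d[1L], "x", d[2L], "px,", object@zCount, "z section(s),",
      object@pixelSizeNM, "nm/px,", object@bitDepth, "bit\n")
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
})

#' @rdname maxProjection
#' @aliases maxProjection,CellImage-method
setMethod("maxProjection", "CellImage", function(x) {
  proj <- lapply(x@channels, function(ch) {
    if (length(dim(ch)) == 3L) apply(ch, c(1L, 2L), max) else ch
  })
  new("CellImage", channels = proj, zCount = 1L,
      pixelSizeNM = x@pixelSizeNM, bitDepth = x@bitDepth)
})

#' Read a multichannel TIFF into a CellImage
#'
#' Reads a (multi-page) TIFF and assigns channel roles to pages. Pages are
#' assumed ordered channel-major: for C channels and Z sections the file
#' holds C*Z pages as (c1z1, c2z1, ..., c1z2, ...) when
#' \code{interleaved = TRUE} (default) or (c1z1..c1zZ, c2z1..) otherwise.
#' Intensities are rescaled from the [0,1] range the TIFF reader returns to
#' the \code{0 .. 2^bitDepth - 1} acquisition scale.
#'
#' @param path TIFF file path.
#' @param channelMap character vector of role names, one per channel, in
#'   page order.
#' @param pixelSizeNM lateral pixel size in nanometres (required; TIFF
#'   resolution tags are not trusted).
#' @param bitDepth acquisition bit depth, default 8.
#' @param interleaved page ordering, see Details.
#' @return a [CellImage-class]
#' @export
readCellImage <- function(path, channelMap, pixelSizeNM, bitDepth = 8L,
                          interleaved = TRUE) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  if (missing(pixelSizeNM) || is.null(pixelSizeNM) || !is.finite(pixelSizeNM) ||
      pixelSizeNM <= 0)
    stop("pixelSizeNM must be supplied as a positive number")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse accidental RGB
    p * (2^bitDepth - 1)
  })
  nc <- length(channelMap)
  if (length(pages) %% nc != 0L)
    stop("page count (", length(pages), ") is not a multiple of the ",
         nc, " mapped channels")
  nz <- length(pages) %/% nc
  chans <- vector("list", nc)
  names(chans) <- channelMap
  for (ci in seq_len(nc)) {
    idx <- if (interleaved) seq(ci, length(pages), by = nc)
           else seq((ci - 1L) * nz + 1L, length.out = nz)
    stack <- pages[idx]
    chans[[ci]] <- if (nz == 1L) stack[[1L]]
                   else array(unlist(stack), dim = c(dim(stack[[1L]]), nz))
  }
  CellImage(chans, pixelSizeNM = pixelSizeNM, bitDepth = bitDepth)
}

#' Write a CellImage to a multichannel TIFF
#'
#' Inverse of [readCellImage()]: pages are written channel-major interleaved
#' (all channels of z1, then z2, ...), 16-bit, intensities rescaled to [0,1]
#' by the image bit depth.
#'
#' @param x a [CellImage-class]
#' @param path output TIFF path
#' @return \code{path}, invisibly
#' @export
writeCellImage <- function(x, path) {
  maxv <- 2^x@bitDepth - 1
  pages <- list()
  for (z in seq_len(x@zCount)) {
    for (ch in x@channels) {
      pl <- if (length(dim(ch)) == 3L) ch[, , z] else ch
      pages[[length(pages) + 1L]] <- pmax(pmin(pl / maxv, 1), 0)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
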