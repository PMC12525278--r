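#' Channel names of a CellImage
#' @param x a [CellImage-class]
#' @return character vector of channel role names
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Extract one channel
#' @param x a [CellImage-class]
#' @param role channel role name
#' @return numeric matrix or array
#' @export
setGeneric("getChannel", function(x, role) standardGeneric("getChannel"))

#' Number of z sections
#' @param x a [CellImage-class]
#' @return integer
#' @export
setGeneric("zCount", function(x) standardGeneric("zCount"))

#' Lateral pixel size in nanometres
#' @param x a [CellImage-class]
#' @return numeric scalar (nm)
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Maximum-intensity projection over z
#'
#' Collapses a z-stack to a single plane per channel by taking, for every
#' pixel, the maximum intensity across sections. Idempotent: projecting a
#' single-plane image returns it unchanged.
#'
#' @param x a [CellImage-class]
#' @return a [CellImage-class] with \code{zCount == 1}
#' @export
setGeneric("maxProjection", function(x) standardGeneric("maxProjection"))
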