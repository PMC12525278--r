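#' @import methods
#' @importFrom stats rnorm rpois runif rbinom rnbinom sd median quantile var
#'   aov TukeyHSD kruskal.test chisq.test shapiro.test t.test wilcox.test
#'   p.adjust pnorm pchisq lm coef predict setNames complete.cases dist
#' @importFrom utils combn head modifyList write.csv read.csv
NULL

#' Multichannel fluorescence cell image
#'
#' Container for one field of view: a set of named intensity channels (all
#' sharing spatial dimensions), the number of z sections, the pixel size and
#' the acquisition bit depth. Channels are stored as numeric arrays indexed
#' \code{[row, col]} (2-D) or \code{[row, col, z]} (3-D) on the raw intensity
#' scale (\code{0 .. 2^bitDepth - 1}).
#'
#' @slot channels named list of numeric arrays, one per channel role
#'   (e.g. \code{LAMP1}, \code{TGN46}, \code{GALA}, \code{P62},
#'   \code{LYSOSENSOR}, \code{DAPI}).
#' @slot zCount integer, number of z sections.
#' @slot pixelSizeNM positive numeric, lateral pixel size in nanometres.
#' @slot bitDepth integer, bits per pixel of the source acquisition.
#'
#' @seealso [CellImage()], [maxProjection()], [segmentChannel()]
#' @export
setClass("CellImage",
  representation(
    channels   = "list",
    zCount     = "integer",
    pixelSizeNM = "numeric",
    bitDepth   = "integer"
  )
)

setValidity("CellImage", function(object) {
  msg <- character()
  ch <- object@channels
  if (length(ch) == 0L) msg <- c(msg, "at least one channel is required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
    msg <- c(msg, "channels must have unique non-empty names")
  dims <- lapply(ch, dim)
  if (length(dims) > 1L && !all(vapply(dims[-1L], identical, logical(1), dims[[1L]])))
    msg <- c(msg, "all channels must share spatial dimensions")
  if (any(vapply(ch, function(x) any(x < 0, na.rm = TRUE), logical(1))))
    msg <- c(msg, "intensities must be non-negative")
  if (length(object@pixelSizeNM) != 1L || !is.finite(object@pixelSizeNM) ||
      object@pixelSizeNM <= 0)
    msg <- c(msg, "pixelSizeNM must be a single positive number")
  nz <- if (length(dims)) {
    d <- dims[[1L]]
    if (length(d) >= 3L) d[3L] else 1L
  } else 1L
  if (length(object@zCount) != 1L || object@zCount < 1L || object@zCount != nz)
    msg <- c(msg, "zCount must match the third channel dimension (1 for planes)")
  if (length(msg)) msg else TRUE
})

#' Construct a CellImage
#'
#' @param channels named list of 2-D matrices or 3-D arrays (row, col, z).
#' @param pixelSizeNM lateral pixel size in nanometres.
#' @param bitDepth acquisition bit depth (default 8, as for hybrid-detector
#'   confocal exports).
#' @return A [CellImage-class] object.
#' @examples
#' img <- CellImage(list(LAMP1 = matrix(runif(64, 0, 255), 8, 8)), pixelSizeNM = 40)
#' zCount(img)
#' @export
CellImage <- function(channels, pixelSizeNM, bitDepth = 8L) {
  channels <- lapply(channels, function(x) {
    if (is.matrix(x) || (is.array(x) && length(dim(x)) == 3L)) x
    else stop("each channel must be a 2-D matrix or 3-D array")
  })
  d <- dim(channels[[1L]])
  z <- if (length(d) >= 3L) d[3L] else 1L
  new("CellImage", channels = channels, zCount = as.integer(z),
      pixelSizeNM = as.numeric(pixelSizeNM), bitDepth = as.integer(bitDepth))
}

#' KDA scoring rubric
#'
#' Ordered threshold tables mapping each raw variant annotation to an integer
#' component score, one table per criterion of the knowledge-driven analysis
#' (KDA). Every table is total: any raw value (including missing) maps to
#' exactly one integer. The default rubric ([defaultRubric()]) is fitted to
#' the published score table and every cut-point is configurable; rubrics
#' round-trip through YAML via [readRubric()] / [writeRubric()].
#'
#' @slot criteria named list, one entry per criterion in
#'   \code{kdaCriteria()}; each entry carries the mapping parameters and a
#'   \code{missing} score.
#' @seealso [defaultRubric()], [scoreComponent()], [scoreVariants()]
#' @export
setClass("KDARubric", representation(criteria = "list"))

setValidity("KDARubric", function(object) {
  need <- kdaCriteria()
  have <- names(object@criteria)
  if (!setequal(have, need))
    return(paste("rubric must define exactly the criteria:",
                 paste(need, collapse = ", ")))
  for (nm in need) {
    cr <- object@criteria[[nm]]
    if (!is.list(cr) || is.null(cr$missing))
      return(sprintf("criterion '%s' must be a list with a 'missing' score", nm))
    rng <- cr$range
    if (is.null(rng) || length(rng) != 2L || rng[1L] > rng[2L])
      return(sprintf("criterion '%s' must declare a min..max score range", nm))
  }
  TRUE
})

#' Synthetic-data generator preset
#'
#' Distribution parameters for one experimental group (control or patient
#' line) from which the synthetic image and variant generators sample, plus
#' the group's target summary statistics. Presets are versioned and
#' serializable so a stored preset plus a seed fully determines its output.
#'
#' @slot group group label, e.g. \code{"CT"} or \code{"PD-302"}.
#' @slot params named list of distribution parameters (diameters, counts,
#'   clustering, colocalized fraction, Golgi geometry, puncta rates,
#'   intensity scales, noise model, per-group n).
#' @slot targets named numeric vector of the group summary statistics the
#'   preset is calibrated to recover.
#' @slot version preset schema version string.
#' @seealso [groupPreset()], [makeCellImage()], [makeVariantTable()]
#' @export
setClass("GeneratorPreset",
  representation(group = "character", params = "list",
                 targets = "numeric", version = "character"))

setValidity("GeneratorPreset", function(object) {
  p <- object@params
  msg <- character()
  sc <- unlist(p[c("pixel_size_nm", "diameter_mean_nm", "diameter_sd_nm")],
               use.names = FALSE)
  if (any(!is.finite(sc)) || any(sc <= 0))
    msg <- c(msg, "scales must be positive")
  nn <- unlist(p[c("psf_sigma_px", "read_noise_sd", "poisson_gain")],
               use.names = FALSE)
  if (any(!is.finite(nn)) || any(nn < 0))
    msg <- c(msg, "noise parameters must be non-negative")
  fr <- unlist(p[c("coloc_fraction", "golgi_fragmented_prob")], use.names = FALSE)
  if (any(fr < 0 | fr > 1))
    msg <- c(msg, "fractions must lie in [0,1]")
  if (length(msg)) msg else TRUE
})
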