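## Simulation-recovery drivers: generate a group's synthetic images with a
## preset and push them through the measurement operators, aggregating per
## cell, then per replicate, then across replicates.

.subSeeds <- function(seed, n) .withSeed(seed, sample.int(2147483646L, n))

#' Recover lysosome diameters from synthetic images
#'
#' Generates \code{replicates} lysosome fields with the preset, measures
#' every segmented object with the peak-distance estimator, and aggregates:
#' per-replicate means, the grand mean across replicates, and all
#' per-object values. Extra fields are generated per replicate until the
#' minimum object count is reached.
#'
#' @param preset a [GeneratorPreset-class].
#' @param seed integer seed.
#' @param replicates number of replicates, default the preset's.
#' @param minObjects minimum measured objects per replicate (default the
#'   preset's \code{cells_diameter}, i.e. at least 80).
#' @return list: \code{grandMeanNM}, \code{replicateMeansNM},
#'   \code{diametersNM}, \code{n}.
#' @export
simulateDiameters <- function(preset, seed, replicates = NULL,
                              minObjects = NULL) {
  p <- preset@params
  if (is.null(replicates)) replicates <- p$n_replicates
  if (is.null(minObjects)) minObjects <- p$cells_diameter
  seeds <- .subSeeds(seed, replicates * 4L)
  repMeans <- numeric(replicates); all <- list()
  for (r in seq_len(replicates)) {
    vals <- numeric(0); fi <- 0L
    while (length(vals) < minObjects && fi < 4L) {
      fi <- fi + 1L
      sim <- makeCellImage(preset, seeds[(r - 1L) * 4L + fi], "lysosome")
      m <- measureLysosomes(sim$image)
      vals <- c(vals, m$diameterNM)
    }
    repMeans[r] <- mean(vals)
    all[[r]] <- vals
  }
  list(grandMeanNM = mean(repMeans), replicateMeansNM = repMeans,
       diametersNM = unlist(all), n = length(unlist(all)))
}

#' Recover Golgi fragmented-cell prevalence from synthetic images
#'
#' Generates per-cell Golgi images, segments the TGN and DAPI channels,
#' classifies each cell with [golgiMetrics()]'s default decision rule, and
#' pools the fragmented percentage over replicates.
#'
#' @inheritParams simulateDiameters
#' @param cellsPerReplicate default the preset's (at least 100).
#' @return list: \code{fragmentedPct}, \code{counts} (fragmented, total),
#'   \code{perCell} data.frame (replicate, classification, fragmentCount,
#'   distanceUM, truthFragmented).
#' @export
simulateGolgiPrevalence <- function(preset, seed, replicates = NULL,
                                    cellsPerReplicate = NULL) {
  p <- preset@params
  if (is.null(replicates)) replicates <- p$n_replicates
  if (is.null(cellsPerReplicate)) cellsPerReplicate <- p$cells_golgi
  n <- replicates * cellsPerReplicate
  seeds <- .subSeeds(seed, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- makeCellImage(preset, seeds[i], "golgi")
    img <- sim$image
    maxv <- 255
    tgn <- getChannel(img, "TGN46"); dapi <- getChannel(img, "DAPI")
    gm <- tgn > otsuThreshold(tgn, maxv)
    nm <- dapi > otsuThreshold(dapi, maxv)
    res <- golgiMetrics(gm, nm, pixelSize(img))
    out[[i]] <- data.frame(
      replicate = (i - 1L) %/% cellsPerReplicate + 1L,
      classification = res$classification,
      fragmentCount = res$fragmentCount, distanceUM = res$nucleusDistanceUM,
      truthFragmented = sim$truth$fragmented)
  }
  perCell <- do.call(rbind, out)
  frag <- sum(perCell$classification == "fragmented_or_beehive")
  list(fragmentedPct = 100 * frag / n, counts = c(fragmented = frag,
       total = n), perCell = perCell)
}

#' Recover the Manders M1 coefficient from synthetic two-channel images
#'
#' Per-cell M1 of the enzyme channel against the Otsu mask of the
#' trans-Golgi channel, aggregated per replicate then across replicates.
#'
#' @inheritParams simulateDiameters
#' @param cellsPerReplicate default the preset's (at least 30).
#' @return list: \code{grandMeanM1}, \code{replicateMeans}, \code{perCell}
#'   data.frame (replicate, m1, overlap, planted).
#' @export
simulateColoc <- function(preset, seed, replicates = NULL,
                          cellsPerReplicate = NULL) {
  p <- preset@params
  if (is.null(replicates)) replicates <- p$n_replicates
  if (is.null(cellsPerReplicate)) cellsPerReplicate <- p$cells_coloc
  n <- replicates * cellsPerReplicate
  seeds <- .subSeeds(seed, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- makeCellImage(preset, seeds[i], "coloc")
    cc <- colocalize(sim$image, "GALA", "TGN46")
    out[[i]] <- data.frame(replicate = (i - 1L) %/% cellsPerReplicate + 1L,
                           m1 = cc[["m1"]], overlap = cc[["overlap"]],
                           planted = sim$truth$plantedFraction)
  }
  perCell <- do.call(rbind, out)
  repMeans <- tapply(perCell$m1, perCell$replicate, mean)
  list(grandMeanM1 = mean(repMeans), replicateMeans = as.numeric(repMeans),
       perCell = perCell)
}

#' Recover lysosomal network porosity from synthetic images
#'
#' Segments the lysosome channel, fills the annulus interiors (a membrane
#' stain outlines organelles whose lumen still belongs to the object), and
#' measures tile porosities over the closed network region.
#'
#' @inheritParams simulateDiameters
#' @param fields number of fields, default 3.
#' @param tilePx tile edge passed to [networkPorosity()], default 50.
#' @return list: \code{meanPorosity}, \code{tilePorosities}.
#' @export
simulatePorosity <- function(preset, seed, fields = 3L, tilePx = 50L) {
  seeds <- .subSeeds(seed, fields)
  tiles <- numeric(0)
  for (i in seq_len(fields)) {
    sim <- makeCellImage(preset, seeds[i], "lysosome")
    ch <- getChannel(sim$image, "LAMP1")
    mask <- ch > otsuThreshold(ch, 255)
    filled <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask))) > 0
    tiles <- c(tiles, networkPorosity(filled, tilePx = tilePx))
  }
  list(meanPorosity = mean(tiles), tilePorosities = tiles)
}

#' Recover LysoSensor relative intensities for a set of groups
#'
#' Generates per-cell LysoSensor images for each group, measures the mean
#' segmented-signal intensity per cell, and normalizes to the control group
#' replicate-wise.
#'
#' @param presets list of [GeneratorPreset-class] (must include the
#'   control).
#' @param seed integer seed.
#' @param replicates,cellsPerReplicate structure; defaults from presets.
#' @param controlGroup control label, default \code{"CT"}.
#' @return data.frame: group, replicate, intensity, relative.
#' @export
simulateLysosensor <- function(presets, seed, replicates = NULL,
                               cellsPerReplicate = 10L,
                               controlGroup = "CT") {
  if (is.null(replicates)) replicates <- presets[[1L]]@params$n_replicates
  rows <- list()
  seeds <- .subSeeds(seed, length(presets) * replicates * cellsPerReplicate)
  k <- 0L
  for (pr in presets) {
    for (r in seq_len(replicates)) {
      for (cidx in seq_len(cellsPerReplicate)) {
        k <- k + 1L
        sim <- makeCellImage(pr, seeds[k], "ph")
        rows[[k]] <- data.frame(group = pr@group, replicate = r,
                                intensity = cellMeanIntensity(sim$image))
      }
    }
  }
  lysosensorRelativeIntensity(do.call(rbind, rows), controlGroup)
}

#' Recover p62 aggregate densities for one group
#'
#' @inheritParams simulateDiameters
#' @param cells number of cells, default the preset's.
#' @return numeric vector of per-cell densities (aggregates per um^2).
#' @export
simulateP62 <- function(preset, seed, cells = NULL) {
  if (is.null(cells)) cells <- preset@params$cells_p62
  seeds <- .subSeeds(seed, cells)
  vapply(seq_len(cells), function(i) {
    sim <- makeCellImage(preset, seeds[i], "p62")
    p62AggregateDensity(getChannel(sim$image, "P62"), sim$truth$cellMask,
                        pixelSize(sim$image))$densityPerUM2
  }, numeric(1))
}
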