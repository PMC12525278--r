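#' Run a pipeline stage
#'
#' Orchestrates the simulate -> morphometry -> stats and prioritize stages
#' as reproducible, file-coupled commands. Every stage writes its outputs
#' plus a \code{manifest.json} recording the command, seed, package
#' version, parameters and an MD5 of each output, so a rerun with the same
#' config reproduces byte-identical tables. Outputs are never overwritten
#' unless \code{config$overwrite} is TRUE.
#'
#' Config fields (a named list, or a YAML file path):
#' \describe{
#'   \item{command}{\code{"simulate"}, \code{"morphometry"},
#'     \code{"stats"}, \code{"prioritize"}.}
#'   \item{seed}{integer, required for simulate.}
#'   \item{out}{output directory.}
#'   \item{preset, cells, assay}{simulate: group label, cell count, assay
#'     name (see [makeCellImage()]).}
#'   \item{images, measures}{morphometry: directory of stage-1 output (its
#'     truth sidecars carry group/assay), measures to run.}
#'   \item{records}{stats: tidy CSV from morphometry.}
#'   \item{annotations, vcf, panel, rubric}{prioritize inputs.}
#' }
#'
#' @param config named list or YAML path.
#' @return invisibly, a list with \code{status} (0 on success) and the
#'   written file paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cmd <- config$command
  if (is.null(cmd) || !cmd %in% c("simulate", "morphometry", "stats",
                                  "prioritize"))
    stop("[config] command must be one of simulate/morphometry/stats/prioritize")
  out <- config$out
  if (is.null(out)) stop("[", cmd, "] an output directory is required")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- switch(cmd,
    simulate    = .stageSimulate(config),
    morphometry = .stageMorphometry(config),
    stats       = .stageStats(config),
    prioritize  = .stagePrioritize(config))
  manifest <- list(
    command = cmd, seed = config$seed,
    package = as.character(utils::packageVersion("lysomorph")),
    parameters = config[setdiff(names(config), c("command", "out"))],
    outputs = lapply(res$files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  tag <- if (!is.null(config$preset)) paste0("-", config$preset) else ""
  mpath <- file.path(out, paste0("manifest-", cmd, tag, ".json"))
  .writeJSON(manifest, mpath, config)
  invisible(list(status = 0L, files = c(res$files, mpath)))
}

.checkOverwrite <- function(path, config) {
  if (file.exists(path) && !isTRUE(config$overwrite))
    stop("[", config$command, "] refusing to overwrite ", path,
         " (set overwrite: true)")
  path
}

.writeJSON <- function(x, path, config) {
  .checkOverwrite(path, config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

.stageSimulate <- function(config) {
  for (f in c("seed", "preset")) if (is.null(config[[f]]))
    stop("[simulate] missing config field: ", f)
  preset <- groupPreset(config$preset)
  assay <- if (is.null(config$assay)) "lysosome" else config$assay
  cells <- if (is.null(config$cells)) 3L else as.integer(config$cells)
  seeds <- .subSeeds(as.integer(config$seed), cells)
  files <- character(0)
  truthAll <- list()
  for (i in seq_len(cells)) {
    sim <- makeCellImage(preset, seeds[i], assay)
    tp <- file.path(config$out,
                    sprintf("%s_%s_cell%03d.tif", preset@group, assay, i))
    .checkOverwrite(tp, config)
    writeCellImage(sim$image, tp)
    tr <- sim$truth
    tr$cellMask <- NULL                      # masks stay out of the JSON
    truthAll[[i]] <- c(list(cell = i, seed = seeds[i], group = preset@group,
                            assay = assay,
                            pixelSizeNM = pixelSize(sim$image),
                            channels = channelNames(sim$image)), tr)
    files <- c(files, tp)
  }
  tj <- .writeJSON(truthAll, file.path(config$out,
                                       sprintf("truth-%s-%s.json",
                                               preset@group, assay)),
                   config)
  list(files = c(files, tj))
}

.stageMorphometry <- function(config) {
  imgDir <- config$images
  if (is.null(imgDir) || !dir.exists(imgDir))
    stop("[morphometry] images directory not found: ",
         if (is.null(imgDir)) "(unset)" else imgDir)
  truthPaths <- list.files(imgDir, "^truth-.*\\.json$", full.names = TRUE)
  if (length(truthPaths) == 0L)
    stop("[morphometry] no truth-*.json sidecar found in ", imgDir)
  meta <- do.call(c, lapply(sort(truthPaths), jsonlite::read_json,
                            simplifyVector = FALSE))
  rows <- list()
  for (m in meta) {
    tp <- file.path(imgDir, sprintf("%s_%s_cell%03d.tif", m$group, m$assay,
                                    m$cell))
    img <- readCellImage(tp, unlist(m$channels), m$pixelSizeNM)
    cid <- sprintf("%s_cell%03d", m$group, m$cell)
    add <- function(measure, value, units)
      rows[[length(rows) + 1L]] <<- data.frame(
        cell_id = cid, group = m$group, measure = measure, value = value,
        units = units, stringsAsFactors = FALSE)
    if (m$assay == "lysosome") {
      dm <- measureLysosomes(img)
      for (v in dm$diameterNM) add("lysosome_diameter", v, "nm")
      por <- tryCatch({
        ch <- getChannel(img, "LAMP1")
        mask <- ch > otsuThreshold(ch, 255)
        filled <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask))) > 0
        networkPorosity(filled)
      }, error = function(e) numeric(0))
      for (v in por) add("network_porosity", v, "%")
    } else if (m$assay == "golgi") {
      tgn <- getChannel(img, "TGN46"); dapi <- getChannel(img, "DAPI")
      gm <- golgiMetrics(tgn > otsuThreshold(tgn, 255),
                         dapi > otsuThreshold(dapi, 255), pixelSize(img))
      add("golgi_fragments", gm$fragmentCount, "count")
      add("golgi_nucleus_distance", gm$nucleusDistanceUM, "um")
      add("golgi_fragmented",
          as.integer(gm$classification == "fragmented_or_beehive"), "flag")
    } else if (m$assay == "coloc") {
      cc <- colocalize(img, "GALA", "TGN46")
      add("manders_m1", cc[["m1"]], "fraction")
      add("overlap_coefficient", cc[["overlap"]], "fraction")
    } else if (m$assay == "ph") {
      add("lysosensor_intensity", cellMeanIntensity(img), "au")
    }
  }
  rec <- do.call(rbind, rows)
  rp <- .checkOverwrite(file.path(config$out, "records.csv"), config)
  write.csv(rec, rp, row.names = FALSE)
  list(files = rp)
}

.stageStats <- function(config) {
  if (is.null(config$records) || !file.exists(config$records))
    stop("[stats] records CSV not found: ",
         if (is.null(config$records)) "(unset)" else config$records)
  rec <- read.csv(config$records, stringsAsFactors = FALSE)
  cmp <- compareGroups(rec, controlGroup = config$control)
  cp <- .checkOverwrite(file.path(config$out, "comparisons.csv"), config)
  write.csv(cmp, cp, row.names = FALSE)
  jp <- .writeJSON(cmp, file.path(config$out, "comparisons.json"), config)
  list(files = c(cp, jp))
}

.stagePrioritize <- function(config) {
  if (is.null(config$annotations))
    stop("[prioritize] an annotations table is required")
  v <- readAnnotatedVariants(config$annotations, vcf = config$vcf)
  panel <- if (!is.null(config$panel)) readGenePanel(config$panel) else NULL
  rubric <- if (!is.null(config$rubric)) readRubric(config$rubric)
            else defaultRubric()
  flt <- excludeBenignPolymorphic(filterVariants(v, panel = panel))
  scored <- rankVariants(scoreVariants(flt, rubric))
  sp <- .checkOverwrite(file.path(config$out, "scores.csv"), config)
  sc <- paste0("score_", kdaCriteria())
  cols <- c(setdiff(names(scored), c(sc, "total", "colorBin")),
            sc, "total", "colorBin")
  out <- scored[, cols]
  out$colorBin <- as.character(out$colorBin)
  write.csv(out, sp, row.names = FALSE)
  jp <- .writeJSON(list(
    n_input = nrow(v), n_scored = nrow(scored),
    top = if (nrow(scored)) scored$geneSymbol[1L] else NA,
    totals = scored$total), file.path(config$out, "report.json"), config)
  list(files = c(sp, jp))
}
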