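#' Generator presets for the study groups
#'
#' Returns the versioned [GeneratorPreset-class] of one experimental group:
#' the healthy control line (CT) or one of the patient fibroblast lines
#' (PD-302, PD-216, PD-212, PD-088). A preset's targets are the group
#' summary statistics the synthetic generator is calibrated to let the
#' morphometry operators recover: lysosome diameter mean/SD (nm), lysosomal
#' network porosity (%), Golgi fragmented-cell prevalence (%), Golgi-nucleus
#' distance and fragment counts, enzyme/trans-Golgi Manders M1, p62
#' aggregate density (per um^2) and LysoSensor relative intensity.
#'
#' Presets are calibrated to the target means for diameter, fragmented
#' prevalence, colocalization, LysoSensor and p62 density; target SDs are
#' approximated by the generator's biological + measurement variance, not
#' matched exactly. Network porosity is calibrated ordinally: the cluster
#' dispersion values come from a calibration sweep and preserve the group
#' ordering, but a rim-stained (annular) rendering bounds the achievable
#' signal coverage, so the printed porosity means themselves are not
#' reproduced (see the vignette for the analysis).
#'
#' @param group one of \code{"CT"}, \code{"PD-302"}, \code{"PD-216"},
#'   \code{"PD-212"}, \code{"PD-088"}.
#' @return a [GeneratorPreset-class].
#' @examples
#' groupPreset("CT")@targets[["diameter_nm"]]
#' @export
groupPreset <- function(group) {
  presets <- .presetTable()
  if (!group %in% names(presets))
    stop("unknown group '", group, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[group]]
}

#' @rdname groupPreset
#' @return \code{presetGroups()}: the available group labels.
#' @export
presetGroups <- function() names(.presetTable())

.presetTable <- function() {
  base <- list(
    # imaging / noise model, shared across groups
    pixel_size_nm = 40,          # lysosome assay (super-resolution scale)
    golgi_pixel_nm = 150, coloc_pixel_nm = 100, p62_pixel_nm = 200,
    psf_sigma_px = 1.2, poisson_gain = 1, read_noise_sd = 2,
    ring_sigma_px = 1.0, ring_amplitude = 170,
    # geometry
    lyso_count = 95, lyso_field_px = 512L, lyso_clusters = 3L,
    min_gap_px = 7, diameter_min_nm = 100,
    golgi_field_px = 320L, nucleus_radii_um = c(7.0, 5.2),
    golgi_blob_r_px = 2.2, coloc_field_px = 128L,
    p62_field_px = 384L, p62_cell_radii_um = c(27, 17),
    # replicate structure
    n_replicates = 3L, cells_diameter = 80L, cells_golgi = 100L,
    cells_coloc = 30L, cells_p62 = 20L, cells_ph = 30L)
  mk <- function(group, targets, extra) {
    new("GeneratorPreset", group = group,
        params = modifyList(base, extra), targets = targets,
        version = "1")
  }
  list(
    "CT" = mk("CT",
      c(diameter_nm = 482.9, diameter_sd = 111.2,
        porosity_pct = 12.83, porosity_sd = 14.07,
        golgi_fragmented_pct = 14.67, golgi_distance_um = 5.98,
        golgi_distance_sd = 2.9, golgi_fragments = 4.12,
        golgi_fragments_sd = 2.83,
        coloc_m1 = 0.36, coloc_sd = 0.12,
        lysosensor = 0.99, lysosensor_sd = 0.08,
        p62_density = 0.022, p62_sd = 0.01),
      list(diameter_mean_nm = 482.9, diameter_sd_nm = 111.2,
           cluster_dispersion_px = 12,
           golgi_fragmented_prob = 0.1467,
           frag_count_mean = 8, unfrag_count_mean = 3.5,
           dist_unfrag_um = c(5.6, 2.8), dist_frag_um = c(8.0, 3.5),
           coloc_fraction = 0.36, coloc_cell_sd = 0.12,
           p62_rate_per_um2 = 0.022, lysosensor_scale = 0.99,
           lysosensor_cell_sd = 0.08)),
    "PD-302" = mk("PD-302",
      c(diameter_nm = 645.8, diameter_sd = 116.7,
        porosity_pct = 48.57, porosity_sd = 26.87,
        golgi_fragmented_pct = 14.67, golgi_distance_um = 5.98,
        golgi_distance_sd = 2.9, golgi_fragments = 4.12,
        golgi_fragments_sd = 2.83,
        coloc_m1 = 0.45, coloc_sd = 0.15,
        lysosensor = 0.91, lysosensor_sd = 0.13,
        p62_density = 0.006, p62_sd = 0.02),
      list(diameter_mean_nm = 645.8, diameter_sd_nm = 116.7,
           cluster_dispersion_px = 46, lyso_count = 90,
           golgi_fragmented_prob = 0.1467,
           frag_count_mean = 8, unfrag_count_mean = 3.5,
           dist_unfrag_um = c(5.6, 2.8), dist_frag_um = c(8.0, 3.5),
           coloc_fraction = 0.45, coloc_cell_sd = 0.15,
           p62_rate_per_um2 = 0.006, lysosensor_scale = 0.91,
           lysosensor_cell_sd = 0.13)),
    "PD-216" = mk("PD-216",
      c(diameter_nm = 749.1, diameter_sd = 175.2,
        porosity_pct = 64.59, porosity_sd = 27.87,
        golgi_fragmented_pct = 82.52, golgi_distance_um = 12.01,
        golgi_distance_sd = 5.0, golgi_fragments = 12.25,
        golgi_fragments_sd = 11.8,
        coloc_m1 = 0.36, coloc_sd = 0.12,
        lysosensor = 0.98, lysosensor_sd = 0.11,
        p62_density = 0.012, p62_sd = 0.01),
      list(diameter_mean_nm = 749.1, diameter_sd_nm = 175.2,
           cluster_dispersion_px = 80, lyso_count = 72,
           golgi_fragmented_prob = 0.8252,
           frag_count_mean = 14.2, unfrag_count_mean = 3.5,
           dist_unfrag_um = c(5.6, 2.8), dist_frag_um = c(13.4, 5.0),
           coloc_fraction = 0.36, coloc_cell_sd = 0.12,
           p62_rate_per_um2 = 0.012, lysosensor_scale = 0.98,
           lysosensor_cell_sd = 0.11)),
    "PD-212" = mk("PD-212",
      c(diameter_nm = 588.2, diameter_sd = 134.7,
        porosity_pct = 55.50, porosity_sd = 27.26,
        golgi_fragmented_pct = 14.67, golgi_distance_um = 5.98,
        golgi_distance_sd = 2.9, golgi_fragments = 4.12,
        golgi_fragments_sd = 2.83,
        coloc_m1 = 0.36, coloc_sd = 0.12,
        lysosensor = 1.08, lysosensor_sd = 0.11,
        p62_density = 0.013, p62_sd = 0.01),
      list(diameter_mean_nm = 588.2, diameter_sd_nm = 134.7,
           cluster_dispersion_px = 60, lyso_count = 85,
           golgi_fragmented_prob = 0.1467,
           frag_count_mean = 8, unfrag_count_mean = 3.5,
           dist_unfrag_um = c(5.6, 2.8), dist_frag_um = c(8.0, 3.5),
           coloc_fraction = 0.36, coloc_cell_sd = 0.12,
           p62_rate_per_um2 = 0.013, lysosensor_scale = 1.08,
           lysosensor_cell_sd = 0.11)),
    "PD-088" = mk("PD-088",
      c(diameter_nm = 443.0, diameter_sd = 111.7,
        porosity_pct = 18.29, porosity_sd = 18.04,
        golgi_fragmented_pct = 14.67, golgi_distance_um = 5.98,
        golgi_distance_sd = 2.9, golgi_fragments = 4.12,
        golgi_fragments_sd = 2.83,
        coloc_m1 = 0.36, coloc_sd = 0.12,
        lysosensor = 1.03, lysosensor_sd = 0.11,
        p62_density = 0.02, p62_sd = 0.01),
      list(diameter_mean_nm = 443.0, diameter_sd_nm = 111.7,
           cluster_dispersion_px = 18,
           golgi_fragmented_prob = 0.1467,
           frag_count_mean = 8, unfrag_count_mean = 3.5,
           dist_unfrag_um = c(5.6, 2.8), dist_frag_um = c(8.0, 3.5),
           coloc_fraction = 0.36, coloc_cell_sd = 0.12,
           p62_rate_per_um2 = 0.02, lysosensor_scale = 1.03,
           lysosensor_cell_sd = 0.11)))
}

setMethod("show", "GeneratorPreset", function(object) {
  cat("GeneratorPreset '", object@group, "' (schema v", object@version,
      ")\n", sep = "")
  t <- object@targets
  cat(sprintf("  targets: diameter %.1f nm, porosity %.1f%%, fragmented %.1f%%, M1 %.2f\n",
              t[["diameter_nm"]], t[["porosity_pct"]],
              t[["golgi_fragmented_pct"]], t[["coloc_m1"]]))
})

#' Read / write a generator preset as YAML
#' @param path YAML file path.
#' @return [readPreset()]: a [GeneratorPreset-class]; [writePreset()]:
#'   \code{path} invisibly.
#' @export
readPreset <- function(path) {
  y <- yaml::read_yaml(path)
  prm <- lapply(y$params, function(v) if (length(v) > 1L) unlist(v) else v)
  new("GeneratorPreset", group = y$group, params = prm,
      targets = unlist(y$targets), version = as.character(y$version))
}

#' @rdname readPreset
#' @param preset a [GeneratorPreset-class].
#' @export
writePreset <- function(preset, path) {
  yaml::write_yaml(list(group = preset@group, version = preset@version,
                        params = preset@params,
                        targets = as.list(preset@targets)), path)
  invisible(path)
}
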