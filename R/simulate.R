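## Synthetic fluorescence image and variant-table generators. Every image
## is rendered noiseless first (ground truth recorded at that stage), then
## passed through a Gaussian PSF and a Poisson-Gaussian camera model.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else on.exit(rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

# PSF blur + Poisson shot noise + Gaussian read noise, clipped to 8-bit
.acquire <- function(plane, p) {
  if (p$psf_sigma_px > 0) plane <- EBImage::gblur(plane, sigma = p$psf_sigma_px)
  plane[plane < 0] <- 0
  if (p$poisson_gain > 0)
    plane <- matrix(rpois(length(plane), plane * p$poisson_gain) /
                      p$poisson_gain, nrow(plane))
  if (p$read_noise_sd > 0)
    plane <- plane + matrix(rnorm(length(plane), 0, p$read_noise_sd),
                            nrow(plane))
  plane[plane < 0] <- 0; plane[plane > 255] <- 255
  round(plane)
}

# draw an annulus (membrane-stained organelle rim) into img. The rim is a
# radial Gaussian; its rendered radius is offset by sigmaTot^2/(2r) so that
# after PSF blurring the intensity peak sits at the true radius r (the
# isotropic PSF shifts a curved ridge inward by approximately that much).
.drawAnnulus <- function(img, ctr, rPx, p) {
  # inward ridge shift of the blurred rim: PSF variance plus a half-weight
  # contribution of the rim width (empirically calibrated on noiseless
  # rings, radii 4-12 px)
  rr <- rPx + (p$psf_sigma_px^2 + 0.5 * p$ring_sigma_px^2) / (2 * rPx)
  w <- ceiling(rr + 4 * p$ring_sigma_px)
  rows <- max(1, round(ctr[1]) - w):min(nrow(img), round(ctr[1]) + w)
  cols <- max(1, round(ctr[2]) - w):min(ncol(img), round(ctr[2]) + w)
  d <- sqrt(outer((rows - ctr[1])^2, (cols - ctr[2])^2, `+`))
  img[rows, cols] <- img[rows, cols] +
    p$ring_amplitude * exp(-(d - rr)^2 / (2 * p$ring_sigma_px^2))
  img
}

# filled Gaussian-edged disc (nucleus, Golgi blob, punctum)
.drawDisc <- function(img, ctr, rPx, amplitude, edge = 1) {
  w <- ceiling(rPx + 4 * edge)
  r0 <- max(1, round(ctr[1]) - w); r1 <- min(nrow(img), round(ctr[1]) + w)
  c0 <- max(1, round(ctr[2]) - w); c1 <- min(ncol(img), round(ctr[2]) + w)
  if (r0 > r1 || c0 > c1) return(img)       # window entirely off the field
  rows <- r0:r1; cols <- c0:c1
  d <- sqrt(outer((rows - ctr[1])^2, (cols - ctr[2])^2, `+`))
  prof <- ifelse(d <= rPx, 1, exp(-(d - rPx)^2 / (2 * edge^2)))
  img[rows, cols] <- pmax(img[rows, cols], amplitude * prof)
  img
}

.drawEllipse <- function(img, ctr, radii, amplitude, edge = 1.5) {
  d <- sqrt(outer(((seq_len(nrow(img)) - ctr[1]) / radii[1])^2,
                  ((seq_len(ncol(img)) - ctr[2]) / radii[2])^2, `+`))
  prof <- ifelse(d <= 1, 1, exp(-((d - 1) * mean(radii))^2 / (2 * edge^2)))
  pmax(img, amplitude * prof)
}

.truncNorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Generate one synthetic cell image
#'
#' Renders the channel set of one assay of one group preset, applies the
#' preset's PSF and Poisson-Gaussian noise model, and returns the image
#' together with the pre-noise ground truth. Deterministic for a given
#' (preset, seed, assay).
#'
#' Assays (each rendered at its own magnification, emulating the separate
#' acquisitions of the corresponding experiments):
#' \describe{
#'   \item{lysosome}{a LAMP1-like membrane channel: annular lysosomes with
#'     diameters drawn from the preset distribution, placed by a
#'     parent-offspring (Thomas-style) clustering process whose dispersion
#'     controls network porosity; 40 nm/px.}
#'   \item{golgi}{TGN46 + DAPI channels: an elliptical nucleus and Golgi
#'     fragments whose count and nucleus distance follow the preset's
#'     class-conditional distributions; 150 nm/px.}
#'   \item{coloc}{enzyme (GALA) + TGN46 channels: the planted fraction of
#'     enzyme intensity inside the Golgi region equals the preset
#'     colocalization target; 100 nm/px.}
#'   \item{p62}{P62 channel plus cell mask: puncta at the preset rate per
#'     cell area; 200 nm/px.}
#'   \item{ph}{LYSOSENSOR channel: puncta whose intensity is scaled by the
#'     preset's relative-acidity factor; 100 nm/px.}
#' }
#'
#' @param preset a [GeneratorPreset-class] (see [groupPreset()]).
#' @param seed integer seed; \code{NULL} uses the current RNG stream.
#' @param assay one of \code{"lysosome"}, \code{"golgi"}, \code{"coloc"},
#'   \code{"p62"}, \code{"ph"}.
#' @return list with elements \code{image} (a [CellImage-class]) and
#'   \code{truth} (assay-specific ground truth recorded before noise).
#' @examples
#' sim <- makeCellImage(groupPreset("CT"), seed = 1, assay = "golgi")
#' sim$truth$fragmentCount
#' @export
makeCellImage <- function(preset, seed = NULL,
                          assay = c("lysosome", "golgi", "coloc", "p62",
                                    "ph")) {
  assay <- match.arg(assay)
  p <- preset@params
  .withSeed(seed, switch(assay,
    lysosome = .simLysosome(p),
    golgi    = .simGolgi(p),
    coloc    = .simColoc(p),
    p62      = .simP62(p),
    ph       = .simPh(p)))
}

.simLysosome <- function(p) {
  n <- p$lyso_count; fld <- p$lyso_field_px
  pxnm <- p$pixel_size_nm
  diams <- .truncNorm(n, p$diameter_mean_nm, p$diameter_sd_nm,
                      lower = p$diameter_min_nm)
  rPx <- diams / 2 / pxnm
  margin <- if (n > 0L) max(rPx) + 6 else 10
  parents <- cbind(runif(p$lyso_clusters, fld * 0.3, fld * 0.7),
                   runif(p$lyso_clusters, fld * 0.3, fld * 0.7))
  pos <- matrix(NA_real_, n, 2L)
  placed <- logical(n)
  for (i in seq_len(n)) {
    # clustered proposals first; fall back to uniform proposals so that
    # placement failure is never correlated with object size
    for (try in seq_len(400L)) {
      cand <- if (try <= 200L) {
        parents[sample.int(p$lyso_clusters, 1L), ] +
          rnorm(2L, 0, p$cluster_dispersion_px)
      } else runif(2L, margin, fld - margin)
      if (any(cand < margin) || any(cand > fld - margin)) next
      prev <- which(placed)
      if (length(prev)) {
        dd <- sqrt(rowSums(sweep(pos[prev, , drop = FALSE], 2L, cand)^2))
        if (any(dd < rPx[prev] + rPx[i] + p$min_gap_px)) next
      }
      pos[i, ] <- cand; placed[i] <- TRUE; break
    }
  }
  img <- matrix(0, fld, fld)
  for (i in which(placed)) img <- .drawAnnulus(img, pos[i, ], rPx[i], p)
  ch <- .acquire(img, p)
  list(image = CellImage(list(LAMP1 = ch), pixelSizeNM = pxnm),
       truth = list(diametersNM = diams[placed], positions = pos[placed, ],
                    requested = n, placed = sum(placed),
                    dispersionPx = p$cluster_dispersion_px))
}

.simGolgi <- function(p) {
  fld <- p$golgi_field_px; pxnm <- p$golgi_pixel_nm
  nucR <- p$nucleus_radii_um * 1000 / pxnm * runif(2L, 0.92, 1.08)
  ctr <- c(fld / 2, fld / 2) + runif(2L, -8, 8)
  fragmented <- runif(1L) < p$golgi_fragmented_prob
  k <- if (fragmented) 6L + rpois(1L, max(p$frag_count_mean - 6, 0.1))
       else sample(1:5, 1L, prob = .countWeights(p$unfrag_count_mean))
  dpar <- if (fragmented) p$dist_frag_um else p$dist_unfrag_um
  theta <- runif(1L, 0, 2 * pi)
  bR <- p$golgi_blob_r_px
  edgeR <- function(a) 1 / sqrt((cos(a) / nucR[1L])^2 + (sin(a) / nucR[2L])^2)
  # cap the distance so the farthest blob stays inside the field
  maxD <- ((fld / 2 - 10) - edgeR(theta)) * pxnm / 1000
  distUM <- .truncNorm(1L, dpar[1L], dpar[2L], lower = 0.3, upper = maxD)
  distPx <- distUM * 1000 / pxnm
  place <- function(dp, a) ctr + (edgeR(a) + dp + bR) * c(cos(a), sin(a))
  centers <- matrix(NA_real_, k, 2L)
  centers[1L, ] <- place(distPx - 2 * bR, theta)   # far edge at distPx
  if (k > 1L) for (j in 2:k) {
    for (try in seq_len(100L)) {
      a <- theta + rnorm(1L, 0, if (fragmented) 0.7 else 0.25)
      dp <- runif(1L, 0.05, 0.85) * distPx
      cand <- place(dp, a)
      if (any(cand < 4) || any(cand > fld - 4)) next
      dd <- sqrt(rowSums(sweep(centers[seq_len(j - 1L), , drop = FALSE],
                               2L, cand)^2))
      if (any(dd < 3 * bR + 3)) next
      centers[j, ] <- cand; break
    }
    if (anyNA(centers[j, ])) centers[j, ] <- place(0.5 * distPx,
                                                   theta + runif(1, -1, 1))
  }
  dapi <- .drawEllipse(matrix(0, fld, fld), ctr, nucR, 150)
  tgn <- matrix(0, fld, fld)
  for (j in seq_len(k)) tgn <- .drawDisc(tgn, centers[j, ], bR, 170)
  list(image = CellImage(list(TGN46 = .acquire(tgn, p),
                              DAPI = .acquire(dapi, p)),
                         pixelSizeNM = pxnm),
       truth = list(fragmented = fragmented, fragmentCount = k,
                    distanceUM = distUM, nucleusRadiiPx = nucR))
}

# weights over counts 1..5 with a given mean (linear tilt, clipped)
.countWeights <- function(mu) {
  w <- pmax(1 + (1:5 - 3) * (mu - 3) / 2, 0.02)
  w / sum(w)
}

.simColoc <- function(p) {
  fld <- p$coloc_field_px; pxnm <- p$coloc_pixel_nm
  f <- .truncNorm(1L, p$coloc_fraction, p$coloc_cell_sd,
                  lower = 0.03, upper = 0.97)
  ctr <- c(fld / 2, fld / 2) + runif(2L, -6, 6)
  tgn <- matrix(0, fld, fld)
  nB <- 4L
  bc <- matrix(rep(ctr, each = nB), nB) + matrix(rnorm(2L * nB, 0, 8), nB)
  for (j in seq_len(nB)) tgn <- .drawDisc(tgn, bc[j, ], 6.5, 160)
  # the planted region uses the same operational definition as the
  # measurement: the Otsu foreground of the (clean) TGN channel
  golMask <- tgn > otsuThreshold(tgn, 255)
  # enzyme channel: fraction f of total intensity inside the Golgi mask,
  # remainder in peripheral puncta well away from the Golgi. The enzyme
  # concentrates in the cisternal cores (squared weight, region eroded by
  # ~2 px) so the PSF does not carry planted intensity past the measured
  # mask boundary.
  core <- EBImage::erode(matrix(as.numeric(golMask), fld),
                         EBImage::makeBrush(5L, "disc")) > 0
  if (!any(core)) core <- golMask
  inside <- (tgn / max(tgn))^2 * core
  outside <- matrix(0, fld, fld)
  np <- 20L; placedP <- 0L
  while (placedP < np) {
    cand <- runif(2L, 8, fld - 8)
    if (sqrt(sum((cand - ctr)^2)) < 34) next
    outside <- .drawDisc(outside, cand, 2.5, 1)
    placedP <- placedP + 1L
  }
  outside[golMask] <- 0
  total <- 6e4
  enz <- inside * (f * total / sum(inside)) +
    outside * ((1 - f) * total / sum(outside))
  # rescale globally (never clip per pixel: clipping would distort the
  # planted intensity fraction)
  if (max(enz) > 240) enz <- enz * (240 / max(enz))
  list(image = CellImage(list(GALA = .acquire(enz, p),
                              TGN46 = .acquire(tgn, p)),
                         pixelSizeNM = pxnm),
       truth = list(plantedFraction = f,
                    trueM1 = sum(enz[golMask]) / sum(enz)))
}

.simP62 <- function(p) {
  fld <- p$p62_field_px; pxnm <- p$p62_pixel_nm
  cellR <- p$p62_cell_radii_um * 1000 / pxnm
  ctr <- c(fld / 2, fld / 2)
  d <- sqrt(outer(((seq_len(fld) - ctr[1]) / cellR[1])^2,
                  ((seq_len(fld) - ctr[2]) / cellR[2])^2, `+`))
  cellMask <- d <= 1
  areaUM2 <- sum(cellMask) * (pxnm / 1000)^2
  k <- rpois(1L, p$p62_rate_per_um2 * areaUM2)
  img <- matrix(0, fld, fld)
  pts <- which(cellMask & d < 0.92, arr.ind = TRUE)
  if (k > 0L) {
    sel <- pts[sample.int(nrow(pts), k), , drop = FALSE]
    for (j in seq_len(k)) img <- .drawDisc(img, sel[j, ], 2, 180)
  }
  list(image = CellImage(list(P62 = .acquire(img, p)), pixelSizeNM = pxnm),
       truth = list(count = k, cellMask = cellMask, cellAreaUM2 = areaUM2,
                    densityPerUM2 = k / areaUM2))
}

.simPh <- function(p) {
  fld <- p$coloc_field_px; pxnm <- p$coloc_pixel_nm
  scale <- .truncNorm(1L, p$lysosensor_scale, p$lysosensor_cell_sd,
                      lower = 0.2)
  img <- matrix(0, fld, fld)
  n <- 25L
  for (j in seq_len(n))
    img <- .drawDisc(img, runif(2L, 10, fld - 10), 3, 120 * scale)
  list(image = CellImage(list(LYSOSENSOR = .acquire(img, p)),
                         pixelSizeNM = pxnm),
       truth = list(intensityScale = scale))
}

#' Generate a ground-truthed annotated variant table
#'
#' Samples synthetic variants whose annotation tiers are drawn first (so
#' the tier is the recorded ground truth) and raw values second, uniformly
#' within the tier. Optionally prepends the published reference rows as
#' fixture entries. Deterministic per seed.
#'
#' @param seed integer seed.
#' @param nVariants number of synthetic variants.
#' @param classFractions named ACMG class probabilities (must sum to 1).
#' @param freqTierFractions probabilities of the rare/low/common frequency
#'   tiers plus \code{nf} (not found).
#' @param predictorAgreement probability that each binary predictor calls a
#'   higher-ACMG variant deleterious.
#' @param includeReference prepend the [referenceVariants()] rows.
#' @return list: \code{variants} (annotated table, see [variant-tables])
#'   and \code{truth} (data.frame of true per-criterion component scores
#'   for the synthetic rows, under the default rubric's tier definitions).
#' @export
makeVariantTable <- function(seed, nVariants = 100L,
                             classFractions = c(B = 0.15, LB = 0.15,
                                                VUS = 0.5, LP = 0.15,
                                                P = 0.05),
                             freqTierFractions = c(rare = 0.3, low = 0.4,
                                                   common = 0.1, nf = 0.2),
                             predictorAgreement = 0.7,
                             includeReference = FALSE) {
  if (abs(sum(classFractions) - 1) > 1e-8) stop("class fractions must sum to 1")
  if (abs(sum(freqTierFractions) - 1) > 1e-8) stop("frequency tier fractions must sum to 1")
  .withSeed(seed, {
    cls <- sample(names(classFractions), nVariants, TRUE, classFractions)
    ftier <- sample(names(freqTierFractions), nVariants, TRUE,
                    freqTierFractions)
    maf <- vapply(ftier, function(t) switch(t,
      rare = runif(1, 1e-8, 5e-6 * 0.999), low = runif(1, 5e-6, 1e-3 * 0.999),
      common = runif(1, 1e-3, 5e-3), nf = NA_real_), numeric(1))
    caddTier <- sample(0:2, nVariants, TRUE, c(0.2, 0.5, 0.3))
    cadd <- ifelse(caddTier == 0L, runif(nVariants, 0, 15),
            ifelse(caddTier == 1L, runif(nVariants, 15.01, 30),
                   runif(nVariants, 30.01, 45)))
    sev <- cls %in% c("LP", "P", "VUS")
    pCall <- ifelse(sev, predictorAgreement, 1 - predictorAgreement)
    bin <- function() ifelse(runif(nVariants) < 0.1, NA_integer_,
                             rbinom(nVariants, 1L, pCall))
    mt <- bin(); pp2 <- bin(); sift <- bin(); fmkl <- bin()
    sai <- ifelse(runif(nVariants) < 0.1, NA_integer_,
                  rbinom(nVariants, 1L, 0.1))
    gerp <- rbinom(nVariants, 1L, 0.6)
    constr <- rbinom(nVariants, 1L, 0.2)
    be <- rbinom(nVariants, 1L, 0.8)
    tags <- vapply(seq_len(nVariants), function(i)
      paste(sample(.pathwayVocab, sample(1:3, 1L)), collapse = "/"),
      character(1))
    df <- data.frame(
      geneSymbol = sprintf("GENE%04d", seq_len(nVariants)),
      proteinChange = sprintf("p.(Xaa%dYaa)", seq_len(nVariants)),
      cdnaChange = sprintf("c.%dA>G", seq_len(nVariants)),
      inheritance = sample(c("M", "F", "de_novo", "unknown"), nVariants, TRUE),
      callerCount = sample(1:3, nVariants, TRUE, c(0.1, 0.2, 0.7)),
      mafNFE = unname(maf), mafAnyPopMax = unname(maf),
      caddPhred = round(cadd, 1), acmgClass = cls,
      consequence = sample(c("missense", "synonymous", "intronic", "lof",
                             "other"), nVariants, TRUE,
                           c(0.7, 0.1, 0.1, 0.05, 0.05)),
      mutationTaster = mt, polyphen2 = pp2, sift = sift, fathmmMKL = fmkl,
      spliceAI = sai, gerp = gerp, constraintFlag = constr,
      brainExpression = be, pathwayTags = tags, stringsAsFactors = FALSE)
    truth <- data.frame(
      acmg = c(B = 1, LB = 1, VUS = 2, LP = 3, P = 3)[cls],
      cadd = caddTier,
      frequency = c(rare = 3, low = 2, common = 1, nf = 3)[ftier],
      mutationtaster = ifelse(is.na(mt), 0L, mt),
      polyphen2 = ifelse(is.na(pp2), 0L, pp2),
      sift = ifelse(is.na(sift), 0L, sift),
      fathmm_mkl = ifelse(is.na(fmkl), 0L, fmkl),
      spliceai = ifelse(is.na(sai), 0L, sai),
      gerp = gerp, constraint = constr, brain_expression = be,
      row.names = NULL)
    truth$total <- rowSums(truth)
    if (includeReference) {
      ref <- referenceVariants()
      refTruth <- attr(ref, "published")
      ref$patient <- NULL
      common <- intersect(names(ref), names(df))
      extra <- setdiff(names(df), names(ref))
      for (nm in extra) ref[[nm]] <- NA
      df <- rbind(ref[names(df)], df)
      truth <- rbind(refTruth, truth)
    }
    list(variants = df, truth = truth)
  })
}
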