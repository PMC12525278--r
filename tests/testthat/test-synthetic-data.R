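test_that("presets exist for every study group and reject unknown labels", {
  expect_setequal(presetGroups(),
                  c("CT", "PD-302", "PD-216", "PD-212", "PD-088"))
  expect_equal(groupPreset("CT")@targets[["diameter_nm"]], 482.9)
  expect_equal(groupPreset("PD-216")@targets[["golgi_fragmented_pct"]],
               82.52)
  expect_gt(groupPreset("PD-212")@targets[["lysosensor"]],
            groupPreset("CT")@targets[["lysosensor"]])
  expect_error(groupPreset("PD-999"), "unknown group")
  # YAML round-trip preserves the sampled output
  path <- withr::local_tempfile(fileext = ".yaml")
  writePreset(groupPreset("CT"), path)
  pr2 <- readPreset(path)
  a <- makeCellImage(groupPreset("CT"), seed = 4, assay = "golgi")
  b <- makeCellImage(pr2, seed = 4, assay = "golgi")
  expect_identical(getChannel(a$image, "TGN46"), getChannel(b$image, "TGN46"))
})

test_that("image generation is bit-identical under a fixed seed", {
  pr <- groupPreset("PD-302")
  for (assay in c("lysosome", "golgi", "coloc", "p62", "ph")) {
    a <- makeCellImage(pr, seed = 77, assay = assay)
    b <- makeCellImage(pr, seed = 77, assay = assay)
    for (ch in channelNames(a$image))
      expect_identical(getChannel(a$image, ch), getChannel(b$image, ch))
    aT <- a$truth; bT <- b$truth; aT$cellMask <- NULL; bT$cellMask <- NULL
    expect_identical(aT, bT)
  }
  c1 <- makeCellImage(pr, seed = 78, assay = "golgi")
  expect_false(identical(getChannel(c1$image, "TGN46"),
                         getChannel(makeCellImage(pr, 77, "golgi")$image,
                                    "TGN46")))
})

test_that("variant tables are deterministic with ground-truth scores and fractions", {
  a <- makeVariantTable(seed = 5, nVariants = 50)
  b <- makeVariantTable(seed = 5, nVariants = 50)
  expect_identical(a, b)
  # ground-truth component scores equal the rubric applied to the raw values
  cards <- scoreVariants(a$variants)
  expect_identical(cards$total, as.integer(a$truth$total))
  # class fractions within the binomial 95% CI at n = 1000
  big <- makeVariantTable(seed = 6, nVariants = 1000,
                          classFractions = c(B = 0.3, LB = 0, VUS = 0.5,
                                             LP = 0.2, P = 0))
  for (cl in c("B", "VUS", "LP")) {
    pHat <- mean(big$variants$acmgClass == cl)
    p0 <- c(B = 0.3, VUS = 0.5, LP = 0.2)[[cl]]
    expect_lt(abs(pHat - p0), 1.96 * sqrt(p0 * (1 - p0) / 1000) + 1e-9)
  }
  expect_error(makeVariantTable(1, classFractions = c(B = 0.5, VUS = 0.1)),
               "sum to 1")
  # the published rows ride along as fixture entries and rescore exactly
  withRef <- makeVariantTable(seed = 7, nVariants = 5,
                              includeReference = TRUE)
  refCards <- scoreVariants(withRef$variants[1:9, ])
  expect_identical(refCards$total,
                   c(12L, 11L, 8L, 12L, 8L, 8L, 13L, 12L, 10L))
})

test_that("an empty preset renders background-only channels", {
  pr <- groupPreset("CT")
  p <- pr@params; p$lyso_count <- 0L
  empty <- new("GeneratorPreset", group = "CT", params = p,
               targets = pr@targets, version = "1")
  sim <- makeCellImage(empty, seed = 3, assay = "lysosome")
  expect_identical(sim$truth$placed, 0L)
  m <- measureLysosomes(sim$image)
  expect_identical(nrow(m), 0L)
})

test_that("noiseless, blur-free rendering recovers every diameter within one pixel", {
  pr <- groupPreset("CT")
  p <- pr@params
  p$psf_sigma_px <- 0; p$read_noise_sd <- 0; p$poisson_gain <- 0
  p$lyso_count <- 40L
  clean <- new("GeneratorPreset", group = "CT", params = p,
               targets = pr@targets, version = "1")
  sim <- makeCellImage(clean, seed = 12, assay = "lysosome")
  lab <- segmentChannel(sim$image, "LAMP1", minObjectPx = 12L)
  expect_identical(max(lab), sim$truth$placed)
  pos <- sim$truth$positions
  for (l in seq_len(max(lab))) {
    px <- which(lab == l, arr.ind = TRUE)
    ctr <- colMeans(px)
    i <- which.min((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2)
    d <- lysosomeDiameter(sim$image, lab, l)
    expect_lt(abs(d$diameterNM - sim$truth$diametersNM[i]), 40)
  }
})

test_that("golgi ground truth drives the rendered morphology", {
  pr <- groupPreset("PD-216")
  hits <- 0L; tot <- 0L
  for (s in 1:25) {
    sim <- makeCellImage(pr, seed = 400 + s, assay = "golgi")
    tgn <- getChannel(sim$image, "TGN46")
    dapi <- getChannel(sim$image, "DAPI")
    gm <- golgiMetrics(tgn > otsuThreshold(tgn, 255),
                       dapi > otsuThreshold(dapi, 255),
                       pixelSize(sim$image))
    tot <- tot + 1L
    hits <- hits + ((gm$classification == "fragmented_or_beehive") ==
                      sim$truth$fragmented)
  }
  expect_gte(hits / tot, 0.9)   # classifier agrees with the planted class
})

test_that("porosity rises monotonically with the dispersion parameter", {
  pr <- groupPreset("CT")
  sweep <- c(10, 25, 45, 70, 100)
  med <- numeric(length(sweep))
  for (k in seq_along(sweep)) {
    p <- pr@params
    p$cluster_dispersion_px <- sweep[k]
    p$lyso_count <- 55L                 # below saturation at low dispersion
    pk <- new("GeneratorPreset", group = "CT", params = p,
              targets = pr@targets, version = "1")
    med[k] <- mean(vapply(1:3, function(s)
      simulatePorosity(pk, seed = 900 + s, fields = 1L,
                       tilePx = 30L)$meanPorosity, numeric(1)))
  }
  expect_true(all(diff(med) > 0))
})
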