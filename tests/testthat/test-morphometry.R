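test_that("Manders M1 matches hand arithmetic and its limits", {
  ref <- matrix(c(1, 2, 3, 4), 1)
  expect_equal(mandersM1(ref, matrix(c(TRUE, TRUE, FALSE, FALSE), 1)), 0.3)
  expect_equal(mandersM1(ref, matrix(TRUE, 1, 4)), 1)
  expect_equal(mandersM1(matrix(c(1, 1, 0, 0), 1),
                         matrix(c(FALSE, FALSE, TRUE, TRUE), 1)), 0)
  expect_equal(mandersM1(matrix(0, 2, 2), matrix(TRUE, 2, 2)), 0)
  expect_error(mandersM1(ref, matrix(TRUE, 2, 2)), "shapes differ")
})

test_that("overlap coefficient matches hand arithmetic and is scale-invariant", {
  expect_equal(overlapCoefficient(matrix(c(1, 0, 1), 1),
                                  matrix(c(1, 1, 0), 1)), 0.5)
  m <- matrix(runif(64), 8, 8)
  expect_equal(overlapCoefficient(m, m), 1)
  a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(0, 0, 2, 3), 2)
  expect_equal(overlapCoefficient(a, b), 0)
  expect_error(overlapCoefficient(matrix(0, 2, 2), matrix(0, 2, 2)),
               "all zero")
  set.seed(314)
  r <- matrix(runif(100), 10); g <- matrix(runif(100), 10)
  base <- overlapCoefficient(r, g)
  for (i in 1:100) {
    s <- runif(2, 0.01, 50)
    expect_equal(overlapCoefficient(r * s[1], g * s[2]), base,
                 tolerance = 1e-12)
  }
})

test_that("peak-distance diameters follow the worked profile and FWHM fallback", {
  res <- profilePeakDistance(c(0, 1, 5, 1, 0, 1, 5, 1, 0), spacingNM = 100)
  expect_equal(res$diameterNM, 400)
  expect_identical(res$method, "peak_distance")
  single <- profilePeakDistance(c(0, 1, 4, 8, 4, 1, 0), spacingNM = 50)
  expect_true(single$unresolved)
  expect_identical(single$method, "fwhm")
  expect_error(profilePeakDistance(c(1, 2), 100), "fewer than 3")
})

test_that("ring diameters are recovered within one pixel across 4-40 px", {
  for (dPx in seq(4, 40, by = 2)) {
    img <- ringImage(dPx / 2, size = max(64, dPx * 3))
    m <- measureLysosomes(img, minObjectPx = 4L)
    expect_identical(nrow(m), 1L)
    expect_lt(abs(m$diameterNM / 40 - dPx), 1)
  }
})

test_that("tile porosity counts pores and drops boundary tiles", {
  region <- matrix(TRUE, 50, 50)
  full <- matrix(TRUE, 50, 50)
  expect_equal(networkPorosity(full, region, tilePx = 50L), 0)
  checker <- outer(1:50, 1:50, function(i, j) (i + j) %% 2 == 0)
  expect_equal(networkPorosity(checker, region, tilePx = 50L), 50)
  # straddling tiles are dropped: a 70x50 region yields one 50-px tile
  region2 <- matrix(FALSE, 100, 60); region2[1:70, 1:50] <- TRUE
  expect_identical(length(networkPorosity(full2 <- matrix(TRUE, 100, 60),
                                          region2, tilePx = 50L)), 1L)
  expect_error(networkPorosity(matrix(TRUE, 30, 30), matrix(TRUE, 30, 30),
                               tilePx = 50L), "smaller than one")
})

test_that("porosity is non-increasing as objects fill a fixed region", {
  set.seed(21)
  region <- matrix(TRUE, 60, 60)
  for (rep in 1:20) {
    mask <- matrix(FALSE, 60, 60)
    prev <- 100
    for (k in 1:12) {
      ctr <- runif(2, 8, 52)
      mask <- mask | discMask(60, ctr, 5)
      cur <- mean(networkPorosity(mask, region, tilePx = 30L))
      expect_lte(cur, prev + 1e-9)
      prev <- cur
    }
  }
})

test_that("dispersed networks score higher porosity than clustered ones", {
  set.seed(33)
  wins <- 0L
  for (rep in 1:10) {
    clustered <- matrix(FALSE, 160, 160)
    dispersed <- matrix(FALSE, 160, 160)
    for (k in 1:50) {
      clustered <- clustered | discMask(160, c(80, 80) + rnorm(2, 0, 16), 6)
      dispersed <- dispersed | discMask(160, runif(2, 20, 140), 6)
    }
    pc <- mean(networkPorosity(clustered, tilePx = 20L, closeRadiusPx = 20L))
    pd <- mean(networkPorosity(dispersed, tilePx = 20L, closeRadiusPx = 20L))
    wins <- wins + (pd > pc)
  }
  expect_identical(wins, 10L)
})

test_that("Golgi metrics match geometry on constructed masks", {
  # disc nucleus radius 10 px, single Golgi pixel 30 px out, 100 nm pixels
  nuc <- discMask(80, c(40, 40), 10)
  gol <- matrix(FALSE, 80, 80); gol[40, 70] <- TRUE
  gm <- golgiMetrics(gol, nuc, pixelSizeNM = 100)
  expect_equal(gm$nucleusDistanceUM, 2.0, tolerance = 0.03)
  expect_identical(gm$fragmentCount, 1L)
  # touching the nucleus boundary gives ~0 distance
  gol2 <- matrix(FALSE, 80, 80); gol2[40, 51] <- TRUE
  expect_lt(golgiMetrics(gol2, nuc, 100)$nucleusDistanceUM, 0.15)
  # three well-separated blobs
  gol3 <- matrix(FALSE, 80, 80)
  for (ctr in list(c(15, 15), c(15, 65), c(70, 40)))
    gol3[discMask(80, ctr, 3)] <- TRUE
  expect_identical(golgiMetrics(gol3, nuc, 100)$fragmentCount, 3L)
  expect_error(golgiMetrics(gol, matrix(FALSE, 80, 80), 100),
               "empty nucleus")
  expect_error(golgiMetrics(matrix(FALSE, 80, 80), nuc, 100), "empty Golgi")
})

test_that("nucleus distance and fragment count equal brute-force pixel oracles", {
  set.seed(55)
  for (i in 1:40) {
    n <- sample(24:64, 1)
    nuc <- discMask(n, runif(2, n * 0.3, n * 0.7), runif(1, 3, n / 5))
    gol <- matrix(runif(n * n) < 0.02, n, n)
    if (!any(gol)) next
    gm <- golgiMetrics(gol, nuc, pixelSizeNM = 100)
    # oracle: double loop over (farthest Golgi pixel, all nucleus pixels)
    nucPx <- which(nuc, arr.ind = TRUE); golPx <- which(gol, arr.ind = TRUE)
    ctr <- colMeans(nucPx)
    far <- golPx[which.max(sqrt((golPx[, 1] - ctr[1])^2 +
                                (golPx[, 2] - ctr[2])^2)), ]
    best <- Inf
    for (j in seq_len(nrow(nucPx)))
      best <- min(best, sqrt(sum((nucPx[j, ] - far)^2)))
    expect_equal(gm$nucleusDistanceUM, best * 0.1, tolerance = 1e-9)
    expect_identical(gm$fragmentCount, floodCount(gol, 4L))
  }
})

test_that("p62 aggregate density counts planted puncta per cell area", {
  # 5 puncta in a 100 um^2 cell at 200 nm pixels -> 0.05 per um^2
  cell <- discMask(100, c(50, 50), sqrt(2500 / pi))  # 2500 px = 100 um^2
  img <- matrix(0, 100, 100)
  for (ctr in list(c(30, 30), c(30, 70), c(70, 30), c(70, 70), c(50, 50)))
    img[discMask(100, ctr, 2)] <- 200
  res <- p62AggregateDensity(img, cell, pixelSizeNM = 200)
  expect_identical(res$count, 5L)
  expect_equal(res$densityPerUM2, 0.05, tolerance = 1e-3)
  zero <- p62AggregateDensity(matrix(0, 100, 100), cell, 200)
  expect_identical(zero$count, 0L)
  expect_equal(zero$densityPerUM2, 0)
  expect_error(p62AggregateDensity(img, matrix(FALSE, 100, 100), 200),
               "empty cell mask")
})

test_that("LysoSensor normalization centers controls at one and scales linearly", {
  cells <- data.frame(group = rep(c("CT", "PD"), each = 6),
                      replicate = rep(rep(1:2, each = 3), 2),
                      intensity = c(10, 11, 12, 20, 21, 22,
                                    20, 22, 24, 40, 42, 44))
  out <- lysosensorRelativeIntensity(cells)
  ct <- out[out$group == "CT", ]
  expect_equal(mean(tapply(ct$relative, ct$replicate, mean)), 1)
  pd <- out[out$group == "PD", ]
  expect_equal(mean(pd$relative), 2, tolerance = 1e-9)  # doubled intensities
  expect_error(lysosensorRelativeIntensity(cells, "NOPE"), "absent")
  bad <- cells; bad$intensity[bad$group == "CT"] <- 0
  expect_error(lysosensorRelativeIntensity(bad), "zero mean")
})

test_that("standard-curve quantification interpolates and flags extrapolation", {
  std <- data.frame(intensity = c(1, 2), ng = c(10, 20))
  expect_equal(standardCurveQuantify(1.5, std)$ng, 15)
  hit <- standardCurveQuantify(2, std)
  expect_equal(hit$ng, 20); expect_false(hit$extrapolated)
  expect_true(standardCurveQuantify(5, std)$extrapolated)
  expect_error(standardCurveQuantify(1, std[1, , drop = FALSE]),
               "at least two")
  expect_error(standardCurveQuantify(1, data.frame(intensity = c(1, 1),
                                                   ng = c(1, 2))),
               "degenerate")
  # Monte-Carlo: mean recovered slope within 2 SEM of truth
  set.seed(88)
  slopes <- replicate(100, {
    x <- c(6.25, 12.5, 20, 50)
    y <- 3 * x + rnorm(4, 0, 4)
    attr(standardCurveQuantify(10, data.frame(intensity = y, ng = x)),
         "slope")
  })
  truthSlope <- 1 / 3
  expect_lt(abs(mean(slopes) - truthSlope),
            2 * sd(slopes) / sqrt(length(slopes)) + 2e-3)
})
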