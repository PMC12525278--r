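test_that("filtering applies the caller/MAF/CADD/panel bounds to the toy table", {
  toy <- toyVariantTable()
  out <- suppressMessages(filterVariants(toy, panel = toyPanel()))
  # hand derivation: row 3 fails callers (2 not > 2), row 4 fails MAF
  # (0.02 >= 0.01), row 5 fails CADD (14.9 <= 15), row 6 off panel,
  # row 8 malformed MAF; rows 1, 2 (NF frequency), 7 (synonymous, CADD 18),
  # 9 (intronic, CADD 16.2), 10 survive
  expect_identical(out$geneSymbol,
                   c("FBXO7", "GLA", "GLB1", "ABL2", "BORCS8"))
  rej <- attr(out, "rejected")
  expect_setequal(rej$row, c(3L, 4L, 5L, 6L, 8L))
  expect_identical(rej$reason[rej$row == 8L], "malformed MAF")
  # boundary values fail the strict bounds
  edge <- toy[1, ]; edge$callerCount <- 2L
  expect_identical(nrow(suppressMessages(filterVariants(edge))), 0L)
  edge <- toy[1, ]; edge$caddPhred <- 15
  expect_identical(nrow(suppressMessages(filterVariants(edge))), 0L)
  edge <- toy[1, ]; edge$mafNFE <- 0.01
  expect_identical(nrow(suppressMessages(filterVariants(edge))), 0L)
})

test_that("filtering is idempotent, order-preserving and case-normalizing", {
  toy <- toyVariantTable()
  panelLower <- tolower(toyPanel())        # casing normalized, not an error
  once <- suppressMessages(filterVariants(toy, panel = panelLower))
  twice <- suppressMessages(filterVariants(once, panel = panelLower))
  expect_identical(once$geneSymbol, twice$geneSymbol)
  expect_true(!is.unsorted(match(once$geneSymbol, toy$geneSymbol)))
})

test_that("benign/likely-benign variants are excluded only when polymorphic", {
  toy <- toyVariantTable()
  out <- excludeBenignPolymorphic(toy)
  # LB at any-population 0.02 (> 1%) excluded; B at 0.002 retained
  expect_false("ABL2" %in% out$geneSymbol)
  expect_true("GLB1" %in% out$geneSymbol)
  df <- data.frame(geneSymbol = c("A", "B", "C", "D"),
                   acmgClass = c("B", "B", "LP", "B"),
                   mafAnyPopMax = c(0.02, 4.46e-3, 0.5, NA))
  kept <- excludeBenignPolymorphic(df)
  expect_identical(kept$geneSymbol, c("B", "C", "D"))
})

test_that("component scoring maps printed raw annotations to printed scores", {
  r <- defaultRubric()
  v <- function(...) data.frame(..., stringsAsFactors = FALSE)
  expect_identical(scoreComponent(v(acmgClass = "VUS"), "acmg", r), 2L)
  expect_identical(scoreComponent(v(acmgClass = "LP"), "acmg", r), 3L)
  expect_identical(scoreComponent(v(acmgClass = "B"), "acmg", r), 1L)
  cadds <- c(24.5, 24.1, 18.3, 34.0, 22.8, 33.0, 35.0, 25.4)
  got <- vapply(cadds, function(x)
    scoreComponent(v(caddPhred = x), "cadd", r), integer(1))
  expect_identical(got, c(1L, 1L, 1L, 2L, 1L, 2L, 2L, 1L))
  # frequency tiers including the not-found rule
  expect_identical(scoreComponent(v(mafNFE = 3.97e-6), "frequency", r), 3L)
  expect_identical(scoreComponent(v(mafNFE = 8.79e-6), "frequency", r), 2L)
  expect_identical(scoreComponent(v(mafNFE = 4.46e-3), "frequency", r), 1L)
  expect_identical(scoreComponent(v(mafNFE = NA_real_), "frequency", r), 3L)
  # missing predictor scores 0; unknown criterion errors
  expect_identical(scoreComponent(v(sift = NA_integer_), "sift", r), 0L)
  expect_error(scoreComponent(v(sift = 1L), "nosuch", r), "unknown criterion")
})

test_that("the published score table is reproduced row by row", {
  v <- referenceVariants()
  pub <- attr(v, "published")
  cards <- scoreVariants(v)
  expect_identical(cards$total, as.integer(pub$total))
  for (cn in kdaCriteria())
    expect_identical(cards[[paste0("score_", cn)]], as.integer(pub[[cn]]))
  fb <- cards[v$geneSymbol == "FBXO7", ]
  expect_identical(as.integer(fb[, paste0("score_", kdaCriteria())]),
                   c(2L, 1L, 3L, 1L, 1L, 1L, 1L, 0L, 1L, 0L, 1L))
  expect_identical(fb$total, 12L)
})

test_that("totals equal the brute-force component sum for random variants", {
  tab <- makeVariantTable(seed = 402, nVariants = 40)$variants
  cards <- scoreVariants(tab)
  r <- defaultRubric()
  for (i in seq_len(nrow(tab))) {
    s <- 0L
    for (cn in kdaCriteria())                 # explicit summation oracle
      s <- s + scoreComponent(tab[i, , drop = FALSE], cn, r)
    expect_identical(cards$total[i], s)
  }
  zero <- data.frame(geneSymbol = "X", acmgClass = NA, caddPhred = 5,
                     mafNFE = 0.5)
  zc <- scoreVariants(zero)
  expect_identical(zc$total, 1L)              # only the common-frequency tier
})

test_that("ranking is a stable sort on (pathway, ACMG, total)", {
  v <- referenceVariants()
  cards <- scoreVariants(v)
  p216 <- cards[cards$patient == "PD-216", ]
  # with the pathway/clinical keys silenced the printed order is by total
  expect_identical(rankVariants(p216, keys = "total")$geneSymbol,
                   c("VPS33B", "GLB1", "DAPK1"))
  expect_identical(rankVariants(p216[2, ]), p216[2, ])
  expect_identical(nrow(rankVariants(cards[0, ])), 0L)
  # oracle: brute-force comparison sort with the same key
  set.seed(11)
  syn <- scoreVariants(makeVariantTable(seed = 31, nVariants = 25)$variants)
  key <- function(df) order(-grepl("(^|/)LY(/|$)", df$pathwayTags),
                            -match(df$acmgClass, c("B", "LB", "VUS", "LP", "P")),
                            -df$total, seq_len(nrow(df)))
  expect_identical(rankVariants(syn)$geneSymbol, syn$geneSymbol[key(syn)])
})

test_that("the color scale is monotone with fixed anchors", {
  expect_identical(as.character(colorBin(15)), "bin15")
  expect_identical(as.character(colorBin(3)), "bin03")
  expect_identical(as.character(colorBin(9)), "bin09")   # middle of 13 bins
  expect_identical(as.character(colorBin(20)), "bin15")  # clamps high
  expect_identical(as.character(colorBin(0)), "bin03")   # clamps low
  b <- colorBin(0:20)
  expect_true(all(diff(as.integer(b)) >= 0))
  expect_identical(length(levels(b)), 13L)
})

test_that("rubrics round-trip through YAML and drive scoring identically", {
  r <- defaultRubric()
  path <- withr::local_tempfile(fileext = ".yaml")
  writeRubric(r, path)
  r2 <- readRubric(path)
  v <- referenceVariants()
  expect_identical(scoreVariants(v, r2)$total, scoreVariants(v, r)$total)
  # cut-points are configurable
  r3 <- defaultRubric(overrides = list(
    cadd = list(type = "breaks", breaks = c(10, 20), scores = c(0, 1, 2),
                missing = 0, range = c(0, 2))))
  expect_identical(scoreComponent(data.frame(caddPhred = 24.5), "cadd", r3), 2L)
})
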