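# Shared in-code fixtures.

# noiseless, blur-free ring image: radial Gaussian rim at radius rPx
ringImage <- function(rPx, size = max(64, ceiling(4 * rPx)),
                      center = c(size / 2 + 0.5, size / 2 + 0.5),
                      rimSigma = 1.0, amplitude = 200) {
  d <- sqrt(outer((seq_len(size) - center[1])^2,
                  (seq_len(size) - center[2])^2, `+`))
  img <- amplitude * exp(-(d - rPx)^2 / (2 * rimSigma^2))
  CellImage(list(LAMP1 = img), pixelSizeNM = 40)
}

# disc mask helper
discMask <- function(size, center, r) {
  d <- sqrt(outer((seq_len(size) - center[1])^2,
                  (seq_len(size) - center[2])^2, `+`))
  d <= r
}

# brute-force connected components by BFS (oracle for labeling)
floodCount <- function(mask, connectivity = 4L) {
  nb <- if (connectivity == 4L)
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else as.matrix(expand.grid(-1:1, -1:1))[-5, ]
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  count <- 0L
  idx <- which(mask != 0, arr.ind = TRUE)
  for (s in seq_len(nrow(idx))) {
    if (seen[idx[s, 1], idx[s, 2]]) next
    count <- count + 1L
    queue <- list(idx[s, ])
    seen[idx[s, 1], idx[s, 2]] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        q <- p + nb[k, ]
        if (q[1] < 1 || q[2] < 1 || q[1] > nrow(mask) || q[2] > ncol(mask))
          next
        if (mask[q[1], q[2]] != 0 && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  count
}

# hand-built 10-variant toy table exercising every filter rule
toyVariantTable <- function() {
  data.frame(
    geneSymbol = c("FBXO7", "GLA", "GBA1", "LRRK2", "VPS33B",
                   "OFFPANEL1", "GLB1", "DAPK1", "ABL2", "BORCS8"),
    proteinChange = sprintf("p.(Var%d)", 1:10),
    cdnaChange = sprintf("c.%dA>G", 1:10),
    inheritance = "unknown",
    callerCount = c(3L, 3L, 2L, 3L, 3L, 3L, 3L, 3L, 3L, 3L),
    mafNFE = c(0.005, NA, 0.001, 0.02, 0.005, 0.001, 0.002, 1.5,
               0.0005, 0.004),
    mafAnyPopMax = c(0.005, NA, 0.001, 0.02, 0.005, 0.001, 0.002, 1.5,
                     0.02, 0.004),
    caddPhred = c(16, 25, 20, 22, 14.9, 30, 18, 20, 16.2, 17),
    acmgClass = c("VUS", "VUS", "LP", "VUS", "VUS", "LP", "B", "VUS",
                  "LB", "VUS"),
    consequence = c("missense", "missense", "missense", "missense",
                    "missense", "missense", "synonymous", "missense",
                    "intronic", "missense"),
    mutationTaster = 1L, polyphen2 = 1L, sift = 0L, fathmmMKL = 1L,
    spliceAI = 0L, gerp = 1L, constraintFlag = 0L, brainExpression = 1L,
    pathwayTags = c("LY", "LY/ATP", "LY", "NR", "GLG", "LY", "LY", "ATP",
                    "NR", "LY"),
    stringsAsFactors = FALSE)
}

toyPanel <- function() c("FBXO7", "GLA", "GBA1", "LRRK2", "VPS33B",
                         "GLB1", "DAPK1", "ABL2", "BORCS8")
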