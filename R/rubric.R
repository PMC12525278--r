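#' Names of the eleven KDA criteria
#'
#' @return character vector, in the column order of the published score
#'   table.
#' @export
kdaCriteria <- function() {
  c("acmg", "cadd", "frequency", "mutationtaster", "polyphen2", "sift",
    "fathmm_mkl", "spliceai", "gerp", "constraint", "brain_expression")
}

# variant-table column consulted by each criterion
.criterionColumn <- c(
  acmg = "acmgClass", cadd = "caddPhred", frequency = "mafNFE",
  mutationtaster = "mutationTaster", polyphen2 = "polyphen2", sift = "sift",
  fathmm_mkl = "fathmmMKL", spliceai = "spliceAI", gerp = "gerp",
  constraint = "constraintFlag", brain_expression = "brainExpression")

#' The default KDA rubric
#'
#' Component cut-points reconstructed to be consistent with every row of the
#' published score table (the original appendix rubric is not public), with
#' every cut-point configurable:
#' \itemize{
#'   \item ACMG: B/LB = 1, VUS = 2, LP/P = 3.
#'   \item CADD PHRED: (15, 30] = 1, > 30 = 2, otherwise 0.
#'   \item Frequency (gnomAD NFE): > 1e-3 = 1, [5e-6, 1e-3) = 2, < 5e-6 or
#'     not found = 3.
#'   \item MutationTaster, PolyPhen-2, SIFT, FATHMM-MKL, SpliceAI: binary
#'     deleterious call, 0/1.
#'   \item GERP: score above \code{gerpMin} (default 2) = 1; 0/1 flags pass
#'     through.
#'   \item Constraint: missense Z >= \code{zMin} (3.09) or pLI >=
#'     \code{pliMin} (0.9) = 1; a supplied 0/1 flag passes through.
#'   \item Brain expression: 0/1 flag.
#' }
#' Missing annotations score the criterion's \code{missing} value (0 for all
#' criteria except frequency, where "not found" is the rarest tier, 3).
#'
#' @param overrides optional named list replacing individual criterion
#'   entries.
#' @return a [KDARubric-class].
#' @examples
#' r <- defaultRubric()
#' scoreComponent(referenceVariants()[1, ], "cadd", r)
#' @export
defaultRubric <- function(overrides = NULL) {
  crit <- list(
    acmg = list(type = "map",
                map = c(B = 1, LB = 1, VUS = 2, LP = 3, P = 3),
                missing = 0, range = c(0, 3)),
    cadd = list(type = "breaks", breaks = c(15, 30), scores = c(0, 1, 2),
                missing = 0, range = c(0, 2)),
    frequency = list(type = "freq_tiers", rareMax = 5e-6, commonMin = 1e-3,
                     scores = c(rare = 3, low = 2, common = 1),
                     missing = 3, range = c(1, 3)),
    mutationtaster = list(type = "binary", missing = 0, range = c(0, 1)),
    polyphen2 = list(type = "binary", missing = 0, range = c(0, 1)),
    sift = list(type = "binary", missing = 0, range = c(0, 1)),
    fathmm_mkl = list(type = "binary", missing = 0, range = c(0, 1)),
    spliceai = list(type = "binary", missing = 0, range = c(0, 1)),
    gerp = list(type = "threshold_or_flag", min = 2, missing = 0,
                range = c(0, 1)),
    constraint = list(type = "constraint", zMin = 3.09, pliMin = 0.9,
                      missing = 0, range = c(0, 1)),
    brain_expression = list(type = "binary", missing = 0, range = c(0, 1)))
  if (!is.null(overrides)) crit <- modifyList(crit, overrides)
  new("KDARubric", criteria = crit)
}

#' Score one criterion of one variant
#'
#' Deterministic map from the variant's raw annotation to the integer
#' component score declared by the rubric; missing annotations take the
#' rubric's missing-value score.
#'
#' @param variant one-row annotated variant \code{data.frame}.
#' @param criterion one of [kdaCriteria()].
#' @param rubric a [KDARubric-class], default [defaultRubric()].
#' @return integer component score.
#' @export
scoreComponent <- function(variant, criterion, rubric = defaultRubric()) {
  if (!criterion %in% kdaCriteria())
    stop("unknown criterion: ", criterion)
  cr <- rubric@criteria[[criterion]]
  col <- .criterionColumn[[criterion]]
  raw <- if (col %in% names(variant)) variant[[col]][1L] else NA
  sc <- switch(cr$type,
    map = {
      if (is.na(raw)) cr$missing
      else {
        if (!raw %in% names(cr$map)) stop("unknown class value: ", raw)
        cr$map[[raw]]
      }
    },
    breaks = {
      if (is.na(raw)) cr$missing
      else cr$scores[findInterval(raw, cr$breaks, left.open = TRUE) + 1L]
    },
    freq_tiers = {
      if (is.na(raw)) cr$missing                       # not found: rarest
      else if (raw < cr$rareMax) cr$scores[["rare"]]
      else if (raw < cr$commonMin) cr$scores[["low"]]
      else cr$scores[["common"]]
    },
    binary = if (is.na(raw)) cr$missing else as.integer(raw != 0),
    threshold_or_flag = {
      if (is.na(raw)) cr$missing
      else if (raw %in% c(0, 1)) as.integer(raw)       # pre-binarized flag
      else as.integer(raw > cr$min)
    },
    constraint = {
      flag <- raw
      if (!is.na(flag)) as.integer(flag != 0)
      else {
        z <- if ("missenseZ" %in% names(variant)) variant$missenseZ[1L] else NA
        pli <- if ("pLI" %in% names(variant)) variant$pLI[1L] else NA
        if (is.na(z) && is.na(pli)) cr$missing
        else as.integer((!is.na(z) && z >= cr$zMin) ||
                        (!is.na(pli) && pli >= cr$pliMin))
      }
    },
    stop("unknown rubric entry type: ", cr$type))
  as.integer(sc)
}

#' Score variants with the KDA rubric
#'
#' Applies [scoreComponent()] over the eleven criteria for every row and
#' appends the component columns, the total and the color bin. The total is
#' exactly the sum of the eleven components.
#'
#' @param variants annotated variant \code{data.frame}.
#' @param rubric a [KDARubric-class].
#' @return a scorecard \code{data.frame}: the input columns plus one integer
#'   \code{score_<criterion>} column per criterion (prefixed so raw
#'   annotation columns like \code{sift} stay distinct), \code{total} and
#'   \code{colorBin}.
#' @examples
#' cards <- scoreVariants(referenceVariants())
#' cards[, c("geneSymbol", "total")]
#' @export
scoreVariants <- function(variants, rubric = defaultRubric()) {
  crits <- kdaCriteria()
  comp <- vapply(seq_len(nrow(variants)), function(i) {
    vapply(crits, function(cn) scoreComponent(variants[i, , drop = FALSE],
                                              cn, rubric), integer(1))
  }, integer(length(crits)))
  comp <- t(matrix(comp, nrow = length(crits)))
  colnames(comp) <- paste0("score_", crits)
  out <- cbind(variants, as.data.frame(comp))
  out$total <- as.integer(rowSums(comp))
  out$colorBin <- colorBin(out$total)
  attr(out, "rejected") <- NULL
  out
}

#' Map a total KDA score to its color bin
#'
#' Ordinal color scale from green (lowest relevant total, 3) to deep red
#' (highest, 15), with 13 evenly spaced interior bins; totals below 3 clamp
#' to the lowest bin and totals of 15 or more to the deepest. Monotone
#' non-decreasing in the total.
#'
#' @param total integer vector of total scores (>= 0).
#' @param low,high scale anchors, defaults 3 and 15.
#' @return ordered factor with \code{high - low + 1} levels named
#'   \code{bin03} (green) .. \code{bin15} (deep red); hex colors in
#'   \code{attr(, "palette")}.
#' @export
colorBin <- function(total, low = 3L, high = 15L) {
  idx <- pmin(pmax(as.integer(round(total)), low), high)
  lev <- sprintf("bin%02d", low:high)
  f <- factor(sprintf("bin%02d", idx), levels = lev, ordered = TRUE)
  attr(f, "palette") <- setNames(
    grDevices::colorRampPalette(c("#1a9850", "#fee08b", "#a50026"))(length(lev)),
    lev)
  f
}

#' Rank scored variants
#'
#' Stable descending sort of scorecards by (lysosomal pathway membership,
#' ACMG severity, total score); ties preserve input order. The key order is
#' an interpretation of the published prioritization prose ("lysosomal
#' signaling pathway, clinical significance, and overall KDA score") and is
#' configurable.
#'
#' @param cards scorecard \code{data.frame} from [scoreVariants()].
#' @param keys character vector, subset/permutation of
#'   \code{c("pathway", "acmg", "total")}.
#' @return the rows of \code{cards}, reordered.
#' @export
rankVariants <- function(cards, keys = c("pathway", "acmg", "total")) {
  if (nrow(cards) == 0L) return(cards)
  keyCols <- list(
    pathway = as.integer(grepl("(^|/)LY(/|$)", cards$pathwayTags)),
    acmg = match(cards$acmgClass, .acmgLevels),
    total = cards$total)
  args <- c(lapply(unname(keyCols[keys]), function(k) -xtfrm(k)),
            list(seq_len(nrow(cards))))
  cards[do.call(order, args), , drop = FALSE]
}

#' Read / write a KDA rubric as YAML
#'
#' @param path YAML file path.
#' @return [readRubric()]: a [KDARubric-class]; [writeRubric()]: \code{path}
#'   invisibly.
#' @export
readRubric <- function(path) {
  y <- yaml::read_yaml(path)
  crit <- lapply(y$criteria, function(cr) {
    if (!is.null(cr$map)) cr$map <- unlist(cr$map)
    if (!is.null(cr$scores)) cr$scores <- unlist(cr$scores)
    if (!is.null(cr$breaks)) cr$breaks <- as.numeric(unlist(cr$breaks))
    if (!is.null(cr$range)) cr$range <- as.numeric(unlist(cr$range))
    cr
  })
  new("KDARubric", criteria = crit)
}

#' @rdname readRubric
#' @param rubric a [KDARubric-class].
#' @export
writeRubric <- function(rubric, path) {
  yaml::write_yaml(list(schema = "kda-rubric/1", criteria = lapply(
    rubric@criteria, function(cr) {
      if (!is.null(cr$map)) cr$map <- as.list(cr$map)
      if (!is.null(cr$scores)) cr$scores <- as.list(cr$scores)
      cr
    })), path)
  invisible(path)
}

setMethod("show", "KDARubric", function(object) {
  cat("KDARubric with", length(object@criteria), "criteria:\n")
  for (nm in names(object@criteria)) {
    cr <- object@criteria[[nm]]
    cat(sprintf("  %-17s %s (missing -> %s, range %d..%d)\n", nm, cr$type,
                cr$missing, cr$range[1L], cr$range[2L]))
  }
})
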