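#' Significance star codes
#'
#' Pure function of the p value: \code{***} below 0.001, \code{**} below
#' 0.01, \code{*} below 0.05, otherwise \code{ns}.
#'
#' @param p numeric vector of p values in [0, 1].
#' @return character vector.
#' @export
starCode <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ifelse(is.na(p), NA_character_,
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
      ifelse(p < 0.05, "*", "ns"))))
}

.groupDescriptives <- function(groups) {
  do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    data.frame(group = g, n = length(x), mean = mean(x), sd = sd(x),
               median = median(x), q25 = unname(quantile(x, 0.25)),
               q75 = unname(quantile(x, 0.75)))
  }))
}

.comparison <- function(measure, groups, test, statistic, p, descriptives) {
  data.frame(measure = measure, groups = paste(groups, collapse = " vs "),
             test = test, statistic = statistic, p_value = p,
             stars = starCode(p), stringsAsFactors = FALSE) ->
    out
  attr(out, "descriptives") <- descriptives
  out
}

#' Choose the statistical test for a design
#'
#' Mirrors the analysis policy used for the group comparisons: normality of
#' every group is gated by the Shapiro-Wilk test (alpha = 0.05, all groups
#' must pass for the parametric branch). Two groups: t-test when normal,
#' Mann-Whitney otherwise. More than two groups: one-way ANOVA with Tukey
#' post hoc when normal, Kruskal-Wallis with Dunn post hoc otherwise.
#' Categorical designs use the chi-squared test of proportions.
#'
#' @param samples named list of numeric vectors (one per group), each with
#'   n >= 3; or \code{NULL} for categorical designs.
#' @param design \code{"continuous"} (default) or \code{"categorical"}.
#' @param alpha Shapiro-Wilk gate, default 0.05.
#' @return test name: \code{"t"}, \code{"mann_whitney"},
#'   \code{"anova_tukey"}, \code{"kruskal_dunn"} or \code{"chi_square"}.
#' @export
chooseTest <- function(samples, design = c("continuous", "categorical"),
                       alpha = 0.05) {
  design <- match.arg(design)
  if (design == "categorical") return("chi_square")
  if (length(samples) < 2L) stop("at least two groups are required")
  ns <- lengths(samples)
  if (any(ns < 3L)) stop("every group needs n >= 3")
  normal <- all(vapply(samples, function(x) {
    if (length(unique(x)) == 1L) return(FALSE)
    shapiro.test(x)$p.value >= alpha
  }, logical(1)))
  if (length(samples) == 2L) {
    if (normal) "t" else "mann_whitney"
  } else {
    if (normal) "anova_tukey" else "kruskal_dunn"
  }
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison. When the pooled sample size is at most
#' \code{exactMax} (default 14) the p value is exact, computed by complete
#' enumeration of all group assignments of the pooled observations (valid
#' with ties); larger samples use the normal approximation with tie
#' correction. Identical constant samples return p = 1 by convention.
#'
#' @param a,b numeric samples, each n >= 3.
#' @param exactMax enumeration bound on \code{length(a) + length(b)}.
#' @param measure label carried into the result, default \code{""}.
#' @param groupNames labels for the two groups.
#' @return a GroupComparison data.frame (one row): test, U statistic,
#'   p value, stars; per-group descriptives in
#'   \code{attr(, "descriptives")}.
#' @export
mannWhitney <- function(a, b, exactMax = 14L, measure = "",
                        groupNames = c("a", "b")) {
  if (length(a) < 3L || length(b) < 3L) stop("each group needs n >= 3")
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  desc <- .groupDescriptives(setNames(list(a, b), groupNames))
  if (length(unique(pooled)) == 1L) {
    message("identical constant samples: p = 1 by convention")
    return(.comparison(measure, groupNames, "mann_whitney", uObs, 1, desc))
  }
  if (N <= exactMax) {
    idx <- combn(N, na)
    uAll <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    mu <- na * nb / 2
    p <- min(1, sum(abs(uAll - mu) >= abs(uObs - mu) - 1e-9) / ncol(idx))
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(na * nb / 12 * ((N + 1) - tieCorr))
    z <- (uObs - mu) / sigma
    p <- 2 * pnorm(-abs(z))
  }
  .comparison(measure, groupNames, "mann_whitney", uObs, p, desc)
}

#' Kruskal-Wallis omnibus test with Dunn post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H, followed by pairwise Dunn z-tests on the
#' pooled mean ranks with multiplicity adjustment (Bonferroni by default).
#'
#' @param groups named list of numeric vectors (>= 3 groups, each n >= 3).
#' @param adjust \code{"bonferroni"} (default), \code{"holm"} or
#'   \code{"none"}.
#' @param measure label carried into the results.
#' @return GroupComparison data.frame: first row the omnibus H, then one
#'   row per pair with the Dunn z and adjusted p value.
#' @export
kruskalDunn <- function(groups, adjust = c("bonferroni", "holm", "none"),
                        measure = "") {
  adjust <- match.arg(adjust)
  if (length(groups) < 3L) stop("Kruskal-Wallis post hoc needs >= 3 groups")
  if (any(lengths(groups) < 3L)) stop("every group needs n >= 3")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- kruskal.test(groups)
  desc <- .groupDescriptives(groups)
  out <- .comparison(measure, names(groups), "kruskal_wallis",
                     unname(kw$statistic), kw$p.value, desc)
  # Dunn z statistics on pooled mean ranks with tie correction
  pooled <- unlist(groups, use.names = FALSE)
  gidx <- rep(names(groups), lengths(groups))
  r <- rank(pooled); N <- length(pooled)
  rbar <- tapply(r, gidx, mean)
  ties <- table(pooled)
  tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- combn(names(groups), 2L)
  zp <- apply(pairs, 2L, function(pr) {
    ni <- length(groups[[pr[1L]]]); nj <- length(groups[[pr[2L]]])
    se <- sqrt((N * (N + 1) / 12 - tieTerm) * (1 / ni + 1 / nj))
    z <- (rbar[[pr[1L]]] - rbar[[pr[2L]]]) / se
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  padj <- p.adjust(zp["p", ], method = adjust)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k)
    .comparison(measure, pairs[, k], "dunn", zp["z", k],
                min(1, padj[k]), NULL)))
  res <- rbind(out, pw)
  attr(res, "descriptives") <- desc
  res
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' @param groups named list of numeric vectors (>= 3 groups, each n >= 3);
#'   at least one group must have non-zero within-group variance.
#' @param measure label carried into the results.
#' @return GroupComparison data.frame: omnibus F row, then one Tukey row
#'   per pair.
#' @export
anovaTukey <- function(groups, measure = "") {
  if (length(groups) < 3L) stop("one-way ANOVA post hoc needs >= 3 groups")
  if (any(lengths(groups) < 3L)) stop("every group needs n >= 3")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (all(vapply(groups, function(x) var(x) == 0, logical(1))))
    stop("zero within-group variance in every group")
  df <- data.frame(y = unlist(groups, use.names = FALSE),
                   g = factor(rep(names(groups), lengths(groups))))
  fit <- aov(y ~ g, data = df)
  sm <- summary(fit)[[1L]]
  desc <- .groupDescriptives(groups)
  out <- .comparison(measure, names(groups), "anova",
                     sm[["F value"]][1L], sm[["Pr(>F)"]][1L], desc)
  tk <- TukeyHSD(fit)$g
  pw <- do.call(rbind, lapply(rownames(tk), function(nm)
    .comparison(measure, strsplit(nm, "-", fixed = TRUE)[[1L]], "tukey",
                tk[nm, "diff"], tk[nm, "p adj"], NULL)))
  res <- rbind(out, pw)
  attr(res, "descriptives") <- desc
  res
}

#' Chi-squared test on a 2x2 proportion table
#'
#' Pearson chi-squared without continuity correction by default (toggle via
#' \code{correct}), as used to compare category prevalences (e.g.
#' fragmented vs unfragmented cells) between two groups.
#'
#' @param counts 2x2 non-negative integer matrix (groups x categories).
#' @param correct apply Yates continuity correction, default FALSE.
#' @param measure label carried into the result.
#' @return GroupComparison data.frame (one row).
#' @export
chiSquareProportions <- function(counts, correct = FALSE, measure = "") {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2L)) stop("a 2x2 count table is required")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in the count table")
  ct <- chisq.test(counts, correct = correct)
  grp <- rownames(counts); if (is.null(grp)) grp <- c("g1", "g2")
  .comparison(measure, grp, "chi_square", unname(ct$statistic), ct$p.value,
              NULL)
}

#' Compare groups of a tidy measurement table
#'
#' Applies [chooseTest()] per measure to a tidy table of per-cell
#' measurements and runs the selected test, returning all comparisons bound
#' together.
#'
#' @param records data.frame with columns \code{group}, \code{measure},
#'   \code{value}.
#' @param controlGroup optional: restrict pairwise designs to control vs
#'   each patient group.
#' @return GroupComparison data.frame.
#' @export
compareGroups <- function(records, controlGroup = NULL) {
  out <- list()
  for (ms in unique(records$measure)) {
    sub <- records[records$measure == ms, ]
    groups <- split(sub$value, sub$group)
    groups <- groups[lengths(groups) >= 3L]
    if (length(groups) < 2L) next
    if (length(groups) == 2L) {
      test <- chooseTest(groups)
      cmp <- if (test == "t") {
        tt <- t.test(groups[[1L]], groups[[2L]])
        .comparison(ms, names(groups), "t", unname(tt$statistic),
                    tt$p.value, .groupDescriptives(groups))
      } else mannWhitney(groups[[1L]], groups[[2L]], measure = ms,
                         groupNames = names(groups))
    } else {
      test <- chooseTest(groups)
      cmp <- if (test == "anova_tukey") anovaTukey(groups, measure = ms)
             else kruskalDunn(groups, measure = ms)
    }
    out[[length(out) + 1L]] <- cmp
  }
  do.call(rbind, out)
}
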