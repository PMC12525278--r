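test_that("the test chooser follows the normality gate and design", {
  set.seed(101)
  g1 <- rnorm(30); g2 <- rnorm(30)
  expect_identical(chooseTest(list(g1, g2)), "t")
  sk1 <- rexp(30)^3; sk2 <- rexp(30)^3
  expect_identical(chooseTest(list(sk1, sk2)), "mann_whitney")
  expect_identical(chooseTest(list(g1, g2, rnorm(30))), "anova_tukey")
  five <- lapply(1:5, function(i) rexp(30)^3)
  expect_identical(chooseTest(five), "kruskal_dunn")
  expect_identical(chooseTest(NULL, design = "categorical"), "chi_square")
  expect_error(chooseTest(list(g1, rnorm(2))), "n >= 3")
  expect_error(chooseTest(list(g1)), "two groups")
})

test_that("Mann-Whitney exact branch matches the enumeration example and oracle", {
  res <- suppressMessages(mannWhitney(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$p_value, 0.1)     # 2 of the 20 arrangements as extreme
  same <- suppressMessages(mannWhitney(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(same$p_value, 1)
  # exact branch equals wilcox.test's exact p for all n_a + n_b <= 10
  set.seed(202)
  for (na in 3:7) for (nb in 3:min(7, 10 - na)) {
    a <- rnorm(na); b <- rnorm(nb, 0.4)      # continuous: tie-free
    ours <- mannWhitney(a, b)$p_value
    ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12,
                 label = sprintf("na=%d nb=%d", na, nb))
  }
  # with ties the enumeration still matches a brute-force permutation oracle
  a <- c(1, 2, 2); b <- c(2, 3, 3)
  pooled <- c(a, b); idx <- combn(6, 3)
  r <- rank(pooled)
  uAll <- colSums(matrix(r[idx], nrow = 3)) - 6
  mu <- 4.5
  pOracle <- sum(abs(uAll - mu) >= abs((sum(r[1:3]) - 6) - mu) - 1e-9) /
    ncol(idx)
  expect_equal(mannWhitney(a, b)$p_value, min(1, pOracle))
  # large samples switch to the tie-corrected normal approximation
  set.seed(203)
  x <- round(rnorm(40), 1); y <- round(rnorm(40, 0.3), 1)
  ours <- mannWhitney(x, y)$p_value
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("Kruskal-Wallis/Dunn behaves on identical, shifted and hand-checked groups", {
  g <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
            c = c(1, 2, 3, 4, 5))
  res <- kruskalDunn(g)
  expect_lt(res$statistic[1], 1e-9)
  expect_true(all(res$stars[-1] == "ns"))
  set.seed(9)
  sh <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30, 50))
  resSh <- kruskalDunn(sh)
  pc <- resSh[resSh$test == "dunn" & grepl("c", resSh$groups), ]
  expect_true(all(pc$p_value < 0.001))
  # omnibus H equals the explicit rank formula (no ties)
  g3 <- list(x = c(1.1, 3.4), y = c(2.2, 5.6), z = c(7.8, 9.9))
  expect_error(kruskalDunn(g3), "n >= 3")
  g3 <- list(x = c(1.1, 3.4, 4.0), y = c(2.2, 5.6, 6.1),
             z = c(7.8, 9.9, 8.5))
  r <- rank(unlist(g3)); N <- 9
  Rsum <- tapply(r, rep(names(g3), each = 3), sum)
  H <- 12 / (N * (N + 1)) * sum(Rsum^2 / 3) - 3 * (N + 1)
  expect_equal(kruskalDunn(g3)$statistic[1], H, tolerance = 1e-9)
})

test_that("ANOVA/Tukey matches hand-computed sums of squares and flags shifts", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8))
  res <- anovaTukey(g)
  means <- vapply(g, mean, numeric(1)); grand <- mean(unlist(g))
  ssb <- 3 * sum((means - grand)^2)
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  Fhand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$statistic[1], Fhand, tolerance = 1e-9)
  set.seed(12)
  sh <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20, 10))
  resSh <- anovaTukey(sh)
  tuk <- resSh[resSh$test == "tukey", ]
  expect_true(all(tuk$p_value[grepl("c", tuk$groups)] < 0.001))
  expect_gt(tuk$p_value[tuk$groups == "b vs a"], 0.05)
  expect_error(anovaTukey(list(a = c(1, 1, 1), b = c(2, 2, 2),
                               c = c(3, 3, 3))), "zero within-group")
})

test_that("the chi-squared proportion test matches the hand formula", {
  even <- matrix(c(30, 30, 70, 70), 2)
  expect_equal(chiSquareProportions(even)$statistic, 0)
  set.seed(77)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 40) + 1, 2)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    hand <- sum((tab - E)^2 / E)
    expect_equal(chiSquareProportions(tab)$statistic, hand,
                 tolerance = 1e-9)
  }
  expect_error(chiSquareProportions(matrix(c(0, 0, 5, 5), 2)),
               "zero marginal")
  expect_error(chiSquareProportions(matrix(1:6, 2)), "2x2")
})

test_that("star codes are a pure function of p and match the figure convention", {
  expect_identical(starCode(c(0.2, 0.04, 0.009, 0.0009)),
                   c("ns", "*", "**", "***"))
  expect_identical(starCode(0.05), "ns")   # boundaries are strict
  expect_identical(starCode(0.01), "*")
  expect_identical(starCode(0.001), "**")
  expect_error(starCode(1.2))
})

test_that("compareGroups dispatches per measure on a tidy table", {
  set.seed(30)
  rec <- rbind(
    data.frame(group = "CT", measure = "m", value = rnorm(20, 1)),
    data.frame(group = "PD", measure = "m", value = rnorm(20, 3)))
  cmp <- compareGroups(rec)
  expect_identical(nrow(cmp), 1L)
  expect_lt(cmp$p_value, 0.001)
  expect_true(cmp$test %in% c("t", "mann_whitney"))
})
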