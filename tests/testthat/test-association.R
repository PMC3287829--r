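test_that("partition retention I matches hand arithmetic", {
  # constant trait: all deviations vanish
  pr0 <- partition_retention_i(rep(2, 8), rep(1:2, each = 4))
  expect_equal(pr0$i_score, 0)
  expect_true(pr0$degenerate)
  # y = (0,0,0,1,1,1) split into the two pure halves:
  # ybar = .5, s^2 = .25, sum n_i^2 (ybar_i - ybar)^2 = 4.5, I = 3
  pr <- partition_retention_i(c(0, 0, 0, 1, 1, 1), rep(1:2, each = 3))
  expect_equal(pr$i_score, 3)
  expect_equal(pr$element_means, c(0, 1))
  expect_equal(pr$overall_sd, 0.5)
  expect_error(partition_retention_i(1:4, 1:3), "equal length")
  td <- tidy(pr)
  expect_equal(td$statistic, 3)
  expect_true(is.na(td$p_value))
})

test_that("partition retention I is invariant to affine trait transforms", {
  set.seed(4)
  y <- rnorm(60)
  lab <- sample(1:5, 60, replace = TRUE)
  i0 <- partition_retention_i(y, lab)$i_score
  expect_equal(partition_retention_i(3.7 * y - 11, lab)$i_score, i0)
  expect_equal(partition_retention_i(-0.2 * y + 5, lab)$i_score, i0)
})

test_that("null mean of I matches the finite-sample closed form", {
  # iid null trait on a fixed partition: E[I] ~= 1 - sum n_i^2 / n^2
  set.seed(8)
  n <- 200
  lab <- rep(1:10, each = 20)
  expected <- 1 - sum(rep(20, 10)^2) / n^2
  istats <- replicate(2000, partition_retention_i(rnorm(n), lab)$i_score)
  se <- sd(istats) / sqrt(length(istats))
  expect_lt(abs(mean(istats) - expected), 3 * se)
})

test_that("one-way ANOVA reproduces the classical F table", {
  # groups (1,2,3) vs (4,5,6): SSB 13.5, SSW 4, F = 13.5 on (1, 4) df
  res <- anova_test(c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))
  expect_equal(res$statistic, 13.5)
  expect_equal(c(res$df1, res$df2), c(1, 4))
  expect_equal(res$p_value, pf(13.5, 1, 4, lower.tail = FALSE))
  # identical groups: F = 0, p = 1
  res0 <- anova_test(c(1, 2, 3, 1, 2, 3), rep(1:2, each = 3))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(anova_test(1:4, rep(1, 4)), "at least 2")
})

test_that("ANOVA with two groups equals the squared two-sample t test", {
  set.seed(12)
  y <- rnorm(30)
  lab <- rep(1:2, 15)
  res <- anova_test(y, lab)
  tt <- t.test(y[lab == 1], y[lab == 2], var.equal = TRUE)
  expect_equal(res$statistic, unname(tt$statistic)^2)
  expect_equal(res$p_value, tt$p.value)
})

test_that("degenerate zero-within-variance ANOVA is flagged at the boundary", {
  res <- anova_test(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_true(res$flag)
  expect_equal(res$p_value, 0)
  res2 <- anova_test(rep(3, 4), c(1, 1, 2, 2))
  expect_true(res2$flag)
  expect_equal(res2$p_value, 1)
})

test_that("ANOVA p-values are uniform under trait permutation", {
  set.seed(19)
  lab <- sample(rep(1:5, each = 20))
  y <- rnorm(100)
  pvals <- replicate(1000, anova_test(sample(y), lab)$p_value)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("chi-square test matches hand-computed Pearson statistics", {
  bal <- yl_from_table(matrix(c(10, 10, 10, 10), 2))
  res <- chisq_test(bal$y, bal$labels)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # perfectly separated 2x2 table: statistic equals n = 40
  sep <- yl_from_table(matrix(c(20, 0, 0, 20), 2))
  res2 <- chisq_test(sep$y, sep$labels)
  expect_equal(res2$statistic, 40)
  expect_equal(res2$df, 1)
  expect_lt(res2$p_value, 1e-9)
  expect_error(chisq_test(c(1, 2, 0), c(1, 2, 1)), "dichotomous")
})

test_that("sparse contingency tables are computed but flagged", {
  sparse <- yl_from_table(matrix(c(30, 1, 2, 0, 1, 1), 2))
  res <- chisq_test(sparse$y, sparse$labels)
  expect_true(res$flag)
  expect_true(is.finite(res$statistic))
})

test_that("Fisher exact p agrees with hypergeometric enumeration", {
  # [[3,0],[0,3]]: only the observed table and its mirror are as improbable
  res <- fisher_exact_rxc(matrix(c(3, 0, 0, 3), 2))
  expect_equal(res$p_value, dhyper(3, 3, 3, 3) + dhyper(0, 3, 3, 3))
  expect_equal(res$p_value, 0.1)
  # proportional rows: the observed table is the most probable, p = 1
  expect_equal(fisher_exact_rxc(matrix(c(4, 8, 2, 4, 6, 12), 2))$p_value, 1)
  expect_error(fisher_exact_rxc(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_error(fisher_exact_rxc(matrix(c(1.5, 1, 2, 1), 2)), "integers")
})

test_that("2x3 Fisher p matches brute-force probability-mass enumeration", {
  tab <- matrix(c(5, 1, 2, 6, 3, 0), nrow = 2)
  # enumerate all tables with the observed margins
  r1 <- sum(tab[1, ]); cs <- colSums(tab); n <- sum(tab)
  logp <- function(x1, x2, x3) {
    lchoose(cs[1], x1) + lchoose(cs[2], x2) + lchoose(cs[3], x3) -
      lchoose(n, r1)
  }
  obs <- logp(tab[1, 1], tab[1, 2], tab[1, 3])
  total <- 0
  for (x1 in 0:min(cs[1], r1)) for (x2 in 0:min(cs[2], r1 - x1)) {
    x3 <- r1 - x1 - x2
    if (x3 >= 0 && x3 <= cs[3]) {
      lp <- logp(x1, x2, x3)
      if (lp <= obs + 1e-7) total <- total + exp(lp)
    }
  }
  expect_equal(fisher_exact_rxc(tab)$p_value, unname(total),
               tolerance = 1e-7)
})

test_that("Fisher and chi-square agree within 2x on large balanced tables", {
  tab <- matrix(c(60, 40, 40, 60), 2)
  yl <- yl_from_table(tab)
  p_chi <- chisq_test(yl$y, yl$labels)$p_value
  p_fis <- fisher_exact_rxc(tab)$p_value
  expect_lt(max(p_chi / p_fis, p_fis / p_chi), 2)
})

test_that("selection rules use Bonferroni and ceiling top-fraction counts", {
  set.seed(30)
  res <- tibble::tibble(gene = sprintf("g%04d", 1:3205),
                        statistic = rnorm(3205),
                        p_value = runif(3205))
  top <- apply_selection(res, "top_fraction", fraction = 0.001)
  expect_equal(sum(top$selected), 4) # ceiling(3.205)
  expect_setequal(which(top$selected),
                  order(-res$statistic, res$gene)[1:4])
  bon <- apply_selection(res, "bonferroni", alpha = 0.05)
  expect_equal(bon$selected, res$p_value <= 0.05 / 3205)
  # n_tests = 1 reduces to the plain level
  one <- apply_selection(res[1:3, ], "bonferroni", alpha = 0.05, n_tests = 1)
  expect_equal(one$selected, res$p_value[1:3] <= 0.05)
  # all p = 1: empty selection
  allone <- apply_selection(dplyr::mutate(res, p_value = 1), "bonferroni")
  expect_false(any(allone$selected))
  expect_error(apply_selection(res, "top_fraction", fraction = 0), "fraction")
})

test_that("top-fraction ties break deterministically by gene id", {
  res <- tibble::tibble(gene = c("gB", "gA", "gC"), statistic = c(1, 1, 0))
  top <- apply_selection(res, "top_fraction", fraction = 1 / 3)
  expect_equal(res$gene[top$selected], "gA")
})

test_that("permutation p-values are seeded and detect real association", {
  set.seed(44)
  lab <- rep(1:4, each = 25)
  y <- rnorm(100) + 0.8 * (lab == 2)
  p1 <- permutation_pvalue(y, lab, "partition_retention", B = 199, seed = 5)
  p2 <- permutation_pvalue(y, lab, "partition_retention", B = 199, seed = 5)
  expect_identical(p1, p2)
  expect_lt(p1$p_value, 0.05)
  # valid lower bound 1/(B+1)
  expect_gte(p1$p_value, 1 / 200)
  null_p <- permutation_pvalue(rnorm(100), lab, "anova", B = 99, seed = 6)
  expect_gt(null_p$p_value, 0.01)
})
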