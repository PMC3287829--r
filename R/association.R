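#' Partition-retention I statistic
#'
#' Measures the association between a trait and a partition of the n
#' individuals as a size-weighted sum of squared element-mean deviations,
#' `I = sum_i n_i^2 (ybar_i - ybar)^2 / (n s^2)`, where `n_i` and `ybar_i`
#' are the size and mean of element i and `ybar`, `s` are the overall mean
#' and standard deviation (denominator n). Under the null hypothesis of no
#' association, I converges to a weighted sum of 1-df chi-square variables
#' with mean 1 as the largest element share goes to 0 (finite-sample null
#' mean `1 - sum_i n_i^2 / n^2`). The measure applies unchanged to
#' dichotomous and quantitative traits, is invariant to affine transforms of
#' the trait, and is robust to sparse partitions where the chi-square test
#' is not. A constant trait gives I = 0 with a degenerate flag.
#'
#' @param y Numeric trait vector of length n (0/1 for dichotomous traits).
#' @param labels Partition labels from [cut_tree()], or any integer vector
#'   of group labels of length n.
#' @return A `partition_retention` object: list with `i_score`,
#'   `element_means`, `overall_mean`, `overall_sd`, `sizes`, `n`, `k` and
#'   `degenerate`. Use [tidy()] for a one-row tibble.
#' @export
#' @examples
#' partition_retention_i(c(0, 0, 0, 1, 1, 1), rep(1:2, each = 3))$i_score # 3
partition_retention_i <- function(y, labels) {
  if (length(y) != length(labels)) abort("y and labels must have equal length")
  n <- length(y)
  sizes <- as.vector(tapply(y, labels, length))
  means <- as.vector(tapply(y, labels, mean))
  ybar <- mean(y)
  s2 <- mean((y - ybar)^2)
  degenerate <- s2 == 0
  i_score <- if (degenerate) 0 else sum(sizes^2 * (means - ybar)^2) / (n * s2)
  structure(list(
    i_score = i_score, element_means = means, overall_mean = ybar,
    overall_sd = sqrt(s2), sizes = sizes, n = n, k = length(sizes),
    degenerate = degenerate
  ), class = "partition_retention")
}

#' @export
print.partition_retention <- function(x, ...) {
  cat(sprintf("Partition retention I = %.4f (n = %d, k = %d%s)\n",
              x$i_score, x$n, x$k, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @rdname partition_retention_i
#' @param x A `partition_retention` object.
#' @param ... Unused.
#' @export
tidy.partition_retention <- function(x, ...) {
  tibble::tibble(method = "partition_retention", statistic = x$i_score,
                 p_value = NA_real_, df = NA_real_, flag = x$degenerate)
}

#' One-way ANOVA of a trait across partition elements
#'
#' Classical one-way F test of equal element means, `(k - 1, n - k)` degrees
#' of freedom, upper-tail p-value from the F distribution. Dichotomous
#' traits are analysed as numeric 0/1. Delegates to
#' [stats::lm()]/[stats::anova()]; singleton elements are legal (they
#' contribute no within-group variance).
#'
#' @param y Numeric trait vector.
#' @param labels Partition labels (at least 2 elements).
#' @return One-row tibble: `method`, `statistic` (F), `df1`, `df2`,
#'   `p_value`, `flag` (`TRUE` when the within-group variance is zero and
#'   the boundary p is reported).
#' @export
anova_test <- function(y, labels) {
  if (length(y) != length(labels)) abort("y and labels must have equal length")
  g <- factor(labels)
  k <- nlevels(g)
  if (k < 2) abort("ANOVA needs at least 2 partition elements")
  n <- length(y)
  within_ss <- sum((y - ave(y, g))^2)
  flag <- FALSE
  if (within_ss == 0) {
    # all element-internal values identical: F degenerates at the boundary
    flag <- TRUE
    means_differ <- length(unique(ave(y, g))) > 1
    return(tibble::tibble(method = "anova",
                          statistic = if (means_differ) Inf else 0,
                          df1 = k - 1, df2 = n - k,
                          p_value = if (means_differ) 0 else 1, flag = flag))
  }
  at <- stats::anova(stats::lm(y ~ g))
  tibble::tibble(method = "anova", statistic = at[["F value"]][1],
                 df1 = at[["Df"]][1], df2 = at[["Df"]][2],
                 p_value = at[["Pr(>F)"]][1], flag = flag)
}

#' Chi-square test of independence between affection status and partition
#'
#' Pearson chi-square on the 2 x k contingency table of a dichotomous trait
#' against partition elements, `k - 1` degrees of freedom, no continuity
#' correction. Sparse tables (any expected cell below 1) are computed but
#' flagged.
#'
#' @param y Dichotomous 0/1 trait vector.
#' @param labels Partition labels (at least 2 elements).
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`, `flag`
#'   (sparse-table indicator).
#' @export
chisq_test <- function(y, labels) {
  if (length(y) != length(labels)) abort("y and labels must have equal length")
  if (!all(y %in% c(0, 1))) abort("chi-square test requires a dichotomous 0/1 trait")
  tab <- table(factor(y, levels = c(0, 1)), labels)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (ncol(tab) < 2) abort("chi-square test needs at least 2 partition elements")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(method = "chisq", statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 flag = any(ct$expected < 1))
}

#' Fisher's exact test for a 2 x c table
#'
#' Exact two-sided p-value with the probability-mass ordering: the sum of
#' the probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table. Used as a
#' diagnostic for partition-versus-genotype cross-tabulations, e.g. when
#' dissecting consistent false positives driven by a causal SNP elsewhere.
#' Delegates to [stats::fisher.test()] (network algorithm).
#'
#' @param tab A 2 x c (c >= 2) nonnegative integer matrix with positive
#'   margins.
#' @param workspace Workspace size forwarded to [stats::fisher.test()].
#' @return One-row tibble: `method`, `p_value`, `nrow`, `ncol`.
#' @export
#' @examples
#' fisher_exact_rxc(matrix(c(3, 0, 0, 3), 2))$p_value # 0.1
fisher_exact_rxc <- function(tab, workspace = 2e7) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) abort("table must hold nonnegative integers")
  if (nrow(tab) < 2 || ncol(tab) < 2) abort("table must be at least 2 x 2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("table has a zero margin")
  }
  ft <- stats::fisher.test(tab, workspace = workspace)
  tibble::tibble(method = "fisher", p_value = ft$p.value,
                 nrow = nrow(tab), ncol = ncol(tab))
}

#' Select genes by Bonferroni or top-fraction rule
#'
#' Two selection modes over a per-gene results table: `"bonferroni"` keeps
#' genes with `p_value <= alpha / n_tests` (family-wise error control), and
#' `"top_fraction"` keeps the `ceiling(fraction * n_genes)` genes with the
#' largest statistic (the default fraction 0.001 is the top 0.1% used to
#' rank the partition-retention I, for which no asymptotic p-value is
#' used). Ties are broken by statistic then gene id, for determinism.
#'
#' @param results Tibble with columns `gene` and, per mode, `p_value` or
#'   `statistic`.
#' @param mode `"bonferroni"` or `"top_fraction"`.
#' @param alpha Family-wise level for Bonferroni, default 0.05.
#' @param fraction Fraction for top-fraction selection, in `(0, 1]`,
#'   default 0.001.
#' @param n_tests Number of tests for the Bonferroni denominator; defaults
#'   to the number of rows of `results`.
#' @return `results` with a logical `selected` column appended.
#' @export
apply_selection <- function(results, mode = c("bonferroni", "top_fraction"),
                            alpha = 0.05, fraction = 0.001, n_tests = NULL) {
  mode <- match.arg(mode)
  results <- tibble::as_tibble(results)
  if (mode == "bonferroni") {
    n_tests <- n_tests %||% nrow(results)
    if (n_tests < 1) abort("n_tests must be at least 1")
    results$selected <- results$p_value <= alpha / n_tests
  } else {
    if (fraction <= 0 || fraction > 1) abort("fraction must lie in (0, 1]")
    n_sel <- ceiling(fraction * nrow(results))
    ord <- order(-results$statistic, results$gene)
    results$selected <- seq_len(nrow(results)) %in% ord[seq_len(n_sel)]
  }
  results
}

#' Permutation p-value for a partition association statistic
#'
#' The asymptotic p-values above are convenient for large simulation
#' studies; for real applications a permutation p-value is preferable.
#' Trait values are permuted across individuals `B` times and
#' `p = (1 + #{perm stat >= observed}) / (1 + B)`.
#'
#' @param y Trait vector.
#' @param labels Partition labels.
#' @param method `"partition_retention"`, `"anova"` or `"chisq"`.
#' @param B Number of permutations, default 999.
#' @param seed Integer seed for the permutation stream.
#' @return One-row tibble: `method`, `statistic` (observed), `p_value`
#'   (permutation), `B`.
#' @export
permutation_pvalue <- function(y, labels,
                               method = c("partition_retention", "anova", "chisq"),
                               B = 999, seed = 1L) {
  method <- match.arg(method)
  stat_fn <- switch(method,
    partition_retention = function(y) partition_retention_i(y, labels)$i_score,
    anova = function(y) anova_test(y, labels)$statistic,
    chisq = function(y) chisq_test(y, labels)$statistic)
  obs <- stat_fn(y)
  perm <- withr_seed(seed, vapply(seq_len(B), function(b) stat_fn(sample(y)),
                                  numeric(1)))
  tibble::tibble(method = method, statistic = obs,
                 p_value = (1 + sum(perm >= obs)) / (1 + B), B = B)
}

# evaluate `expr` under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Write a long-format association results table
#'
#' @param results Tibble with columns such as `gene`, `trait`, `method`,
#'   `k`, `statistic`, `p_value`, `selected`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  readr::write_tsv(tibble::as_tibble(results), path, progress = FALSE)
  invisible(path)
}
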