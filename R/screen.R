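#' Screen configuration
#'
#' Settings shared by [screen_gene()] and [screen_all()].
#'
#' @param ks Partition sizes to sweep, default `5:10`.
#' @param snp_filter `"all"` or `"nonsynonymous"` (see [gene_index()]).
#' @param methods Subset of `"anova"`, `"chisq"`, `"partition_retention"`.
#'   The chi-square test applies only to the dichotomous `Affected` trait
#'   and is silently skipped for quantitative traits.
#' @param traits Subset of `"Q1"`, `"Q2"`, `"Q4"`, `"Affected"`.
#' @param alpha Family-wise level for the Bonferroni rule applied to the
#'   ANOVA and chi-square p-values, default 0.05. The correction divides by
#'   the number of genes tested in each (trait, method, k) screen.
#' @param fraction Top fraction of genes kept when ranking by the
#'   partition-retention I, default 0.001 (the top 0.1%).
#' @param aggregate How per-k selection counts are combined per gene:
#'   `"average"` (arithmetic mean across `ks`, the default ranking) or
#'   `"best"` (maximum across `ks`; the most significant partition size
#'   varies from replicate to replicate, so this is offered as an
#'   alternative).
#' @param seed Integer seed echoed into outputs (the screen itself is
#'   deterministic; the seed feeds optional permutation p-values).
#' @return A `screen_config` list.
#' @export
screen_config <- function(ks = 5:10, snp_filter = c("all", "nonsynonymous"),
                          methods = c("anova", "chisq", "partition_retention"),
                          traits = c("Q1", "Q2", "Q4", "Affected"),
                          alpha = 0.05, fraction = 0.001,
                          aggregate = c("average", "best"), seed = 1L) {
  snp_filter <- match.arg(snp_filter)
  methods <- match.arg(methods, several.ok = TRUE)
  traits <- match.arg(traits, several.ok = TRUE)
  aggregate <- match.arg(aggregate)
  if (any(ks < 2)) abort("partition sizes must be at least 2")
  structure(list(ks = as.integer(ks), snp_filter = snp_filter,
                 methods = methods, traits = traits, alpha = alpha,
                 fraction = fraction, aggregate = aggregate,
                 seed = as.integer(seed)),
            class = "screen_config")
}

# labels for each k cut of one gene's tree: n x length(ks) integer matrix
gene_partitions <- function(geno, columns, ks) {
  D <- similarity_to_distance(gene_similarity(geno, columns = columns))
  tree <- ward_tree(D)
  vapply(ks, function(k) as.integer(cut_tree(tree, k)),
         integer(nrow(geno$dosages)))
}

#' Screen a single gene against a set of traits
#'
#' Runs the whole per-gene pipeline — filter SNPs, sum per-SNP similarity
#' scores, transform to a bounded distance, Ward-cluster, cut at each
#' partition size — then tests partition-trait association with each
#' requested method.
#'
#' @param geno A [geno_matrix()] with gene annotation.
#' @param gene Gene id.
#' @param pheno A single phenotype replicate: a tibble with columns
#'   `individual_id` and the traits, or a `pheno_set` (its first replicate
#'   is used).
#' @param config A [screen_config()].
#' @return Tibble with one row per (trait, method, k): `gene`, `trait`,
#'   `method`, `k`, `statistic`, `p_value`, `flag`.
#' @export
screen_gene <- function(geno, gene, pheno, config = screen_config()) {
  stopifnot(inherits(geno, "geno_matrix"))
  if ("replicate" %in% names(pheno)) {
    pheno <- pheno[pheno$replicate == pheno$replicate[1], ]
  }
  pheno <- pheno[match(geno$individual_ids, pheno$individual_id), ]
  if (anyNA(pheno$individual_id)) abort("phenotypes do not cover all individuals")
  idx <- suppressWarnings(gene_index(geno, config$snp_filter))
  if (!gene %in% names(idx)) {
    abort(paste0("gene has no usable SNPs under this filter: ", gene))
  }
  labels_by_k <- gene_partitions(geno, idx[[gene]], config$ks)
  rows <- purrr::map_dfr(config$traits, function(tr) {
    y <- pheno[[tr]]
    purrr::map_dfr(config$methods, function(m) {
      if (m == "chisq" && tr != "Affected") return(NULL)
      purrr::map_dfr(seq_along(config$ks), function(j) {
        labels <- labels_by_k[, j]
        res <- switch(m,
          anova = anova_test(y, labels)[, c("statistic", "p_value", "flag")],
          chisq = chisq_test(y, labels)[, c("statistic", "p_value", "flag")],
          partition_retention = {
            pr <- partition_retention_i(y, labels)
            tibble::tibble(statistic = pr$i_score, p_value = NA_real_,
                           flag = pr$degenerate)
          })
        dplyr::mutate(res, trait = tr, method = m, k = config$ks[j],
                      .before = 1)
      })
    })
  })
  dplyr::mutate(rows, gene = gene, .before = 1)
}

# vectorised one-way F over replicate columns of Y given fixed labels
fast_anova <- function(Y, labels, sizes) {
  n <- nrow(Y)
  k <- length(sizes)
  S <- rowsum(Y, labels)
  tot <- colSums(Y)
  ssb <- colSums(S^2 / sizes) - tot^2 / n
  sst <- colSums(Y^2) - tot^2 / n
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(statistic = f, p_value = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# vectorised Pearson chi-square on the 2 x k table of 0/1 Y versus labels
fast_chisq <- function(Y, labels, sizes) {
  n <- nrow(Y)
  k <- length(sizes)
  S <- rowsum(Y, labels)            # cases per element per replicate
  r1 <- colSums(Y)                  # total cases per replicate
  e <- outer(sizes, r1) / n
  x2 <- colSums((S - e)^2 / sizes) * n^2 / (r1 * (n - r1))
  list(statistic = x2, p_value = pchisq(x2, k - 1, lower.tail = FALSE))
}

# vectorised partition-retention I: sum_i (S_i - n_i ybar)^2 / (n s^2)
fast_pr <- function(Y, labels, sizes) {
  n <- nrow(Y)
  S <- rowsum(Y, labels)
  tot <- colSums(Y)
  sst <- colSums(Y^2) - tot^2 / n   # = n s^2
  i_score <- colSums((S - outer(sizes, tot / n))^2) / sst
  i_score[sst == 0] <- 0
  list(statistic = i_score, p_value = rep(NA_real_, ncol(Y)))
}

#' Screen every gene across traits, partition sizes and replicates
#'
#' The full screen: each gene's SNPs are collapsed into partitions once
#' (genotypes are fixed), then every phenotype replicate is tested against
#' every partition. A gene is *selected* in a replicate when it passes the
#' Bonferroni threshold (ANOVA, chi-square; level `alpha` over the genes in
#' that screen) or falls in the top `fraction` of genes ranked by the
#' partition-retention I. Selections are counted over replicates per
#' partition size and combined across sizes per `config$aggregate`.
#'
#' @param geno A [geno_matrix()] with gene annotation.
#' @param phenos A `pheno_set` of one or more replicates.
#' @param config A [screen_config()].
#' @return A `gene_screen` object: list with
#'   * `counts`: tibble `gene`, `trait`, `method`, `k`, `count`;
#'   * `summary`: tibble `gene`, `trait`, `method`, `average_count`
#'     (and `detection` = average_count / n_replicates);
#'   * `familywise`: tibble `trait`, `method`, `k`, `replicate`,
#'     `n_selected` — how many genes each screen selected per replicate;
#'   * `skipped`: genes with no usable SNP under the filter;
#'   * `capped`: tibble of (gene, k) where the gene had fewer distinct
#'     genotype profiles than k (the cut is still made; identical profiles
#'     may then share or split elements);
#'   * `n_replicates`, `n_genes`, `config`.
#' @export
screen_all <- function(geno, phenos, config = screen_config()) {
  stopifnot(inherits(geno, "geno_matrix"))
  phenos <- align_phenotypes(phenos, geno)
  idx <- gene_index(geno, config$snp_filter)
  all_genes <- unique(geno$snps$gene[!is.na(geno$snps$gene)])
  skipped <- setdiff(all_genes, names(idx))
  genes <- names(idx)
  G <- length(genes)
  if (!G) abort("no gene has usable SNPs under this filter")
  n <- nrow(geno$dosages)
  reps <- sort(unique(phenos$replicate))
  R <- length(reps)
  ks <- config$ks

  parts <- lapply(idx, function(cols) gene_partitions(geno, cols, ks))
  profiles <- vapply(idx, function(cols) {
    nrow(unique(geno$dosages[, cols, drop = FALSE]))
  }, integer(1))
  capped <- tidyr::expand_grid(gene = genes, k = ks)
  capped <- capped[profiles[capped$gene] < capped$k, ]

  Ymats <- lapply(config$traits, function(tr) {
    matrix(phenos[[tr]], nrow = n, ncol = R,
           dimnames = list(geno$individual_ids, reps))
  })
  names(Ymats) <- config$traits

  counts <- list()
  familywise <- list()
  for (tr in config$traits) {
    Y <- Ymats[[tr]]
    for (m in config$methods) {
      if (m == "chisq" && tr != "Affected") next
      fn <- switch(m, anova = fast_anova, chisq = fast_chisq,
                   partition_retention = fast_pr)
      for (j in seq_along(ks)) {
        stat <- matrix(NA_real_, G, R)
        pval <- matrix(NA_real_, G, R)
        for (g in seq_len(G)) {
          labels <- parts[[g]][, j]
          res <- fn(Y, labels, tabulate(labels, nbins = ks[j]))
          stat[g, ] <- res$statistic
          pval[g, ] <- res$p_value
        }
        if (m == "partition_retention") {
          n_sel <- ceiling(config$fraction * G)
          sel <- matrix(FALSE, G, R)
          for (r in seq_len(R)) {
            ord <- order(-stat[, r], genes)
            sel[ord[seq_len(n_sel)], r] <- TRUE
          }
        } else {
          sel <- pval <= config$alpha / G
        }
        counts[[length(counts) + 1]] <- tibble::tibble(
          gene = genes, trait = tr, method = m, k = ks[j],
          count = rowSums(sel))
        familywise[[length(familywise) + 1]] <- tibble::tibble(
          trait = tr, method = m, k = ks[j], replicate = reps,
          n_selected = colSums(sel))
      }
    }
  }
  counts <- dplyr::bind_rows(counts)
  comb <- if (config$aggregate == "average") mean else max
  summary <- counts |>
    dplyr::group_by(.data$gene, .data$trait, .data$method) |>
    dplyr::summarise(average_count = comb(.data$count), .groups = "drop") |>
    dplyr::mutate(detection = .data$average_count / R)
  structure(list(counts = counts, summary = summary,
                 familywise = dplyr::bind_rows(familywise),
                 skipped = skipped, capped = capped,
                 n_replicates = R, n_genes = G, config = config),
            class = "gene_screen")
}

#' @export
print.gene_screen <- function(x, ...) {
  cat(sprintf("<gene_screen> %d genes x %d replicates; ks = %s\n",
              x$n_genes, x$n_replicates,
              paste(x$config$ks, collapse = ",")))
  cat(sprintf("  traits: %s; methods: %s; filter: %s\n",
              paste(x$config$traits, collapse = ","),
              paste(x$config$methods, collapse = ","), x$config$snp_filter))
  invisible(x)
}

#' @rdname screen_all
#' @param x A `gene_screen`.
#' @param ... Unused.
#' @return `tidy()` returns the per-k selection counts; `glance()` the
#'   per-gene summary averaged across partition sizes.
#' @export
tidy.gene_screen <- function(x, ...) x$counts

#' @rdname screen_all
#' @export
glance.gene_screen <- function(x, ...) x$summary

#' Top-ranked genes of a screen
#'
#' Ranks genes by their selection count combined across partition sizes,
#' for one trait and method.
#'
#' @param screen A [screen_all()] result.
#' @param trait,method Which screen to rank.
#' @param n How many genes, default 10.
#' @return Tibble of the top `n` genes with `average_count` and
#'   `detection` (frequency over replicates).
#' @export
top_genes <- function(screen, trait, method, n = 10) {
  screen$summary |>
    dplyr::filter(.data$trait == !!trait, .data$method == !!method) |>
    dplyr::arrange(dplyr::desc(.data$average_count), .data$gene) |>
    head(n)
}

#' Gene-wise total effect size
#'
#' The total effect of a gene in the simulation model is the sum over its
#' SNPs of MAF times the causal effect, zero for SNPs (and hence genes)
#' with no causal effect. Sample MAFs from the genotype matrix are used.
#'
#' @param truth Truth table (`snp_id`, `trait`, `beta`) from
#'   [simulate_phenotypes()], or a [sim_model()] with a causal map.
#' @param geno A [geno_matrix()] with gene annotation.
#' @param trait Trait whose effects are summed, default `"Q1"`.
#' @return Tibble `gene`, `total_effect`, covering every annotated gene.
#' @export
gene_effect_sizes <- function(truth, geno, trait = "Q1") {
  if (inherits(truth, "sim_model")) truth <- truth$causal
  truth <- if (is.null(truth)) {
    tibble::tibble(snp_id = character(), trait = character(), beta = numeric())
  } else tibble::as_tibble(truth)
  truth <- truth[truth$trait == trait, ]
  unknown <- setdiff(truth$snp_id, geno$snps$snp_id)
  if (length(unknown)) {
    abort(paste0("unknown SNP id(s) in causal map: ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  idx <- match(truth$snp_id, geno$snps$snp_id)
  per_snp <- tibble::tibble(gene = geno$snps$gene[idx],
                            contrib = geno$snps$maf[idx] * truth$beta)
  all_genes <- unique(geno$snps$gene[!is.na(geno$snps$gene)])
  per_snp |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(total_effect = sum(.data$contrib), .groups = "drop") |>
    dplyr::right_join(tibble::tibble(gene = all_genes), by = "gene") |>
    dplyr::mutate(total_effect = dplyr::coalesce(.data$total_effect, 0)) |>
    dplyr::arrange(.data$gene)
}

#' Power against gene-wise effect size
#'
#' Joins per-gene detection frequencies from a screen with the gene-wise
#' total effects of the generating model, for plotting power against
#' effect size.
#'
#' @param screen A [screen_all()] result (or its `summary` tibble plus
#'   `n_replicates` attribute-free; the object form is preferred).
#' @param effects A [gene_effect_sizes()] table.
#' @param trait,method Which screen's detection frequencies to use.
#' @return A `power_curve` tibble: `gene`, `effect`, `detection`, sorted by
#'   effect.
#' @export
power_curve <- function(screen, effects, trait, method) {
  summ <- if (inherits(screen, "gene_screen")) screen$summary else tibble::as_tibble(screen)
  out <- summ |>
    dplyr::filter(.data$trait == !!trait, .data$method == !!method) |>
    dplyr::select("gene", "detection") |>
    dplyr::inner_join(dplyr::rename(effects, effect = "total_effect"),
                      by = "gene") |>
    dplyr::select("gene", "effect", "detection") |>
    dplyr::arrange(.data$effect)
  class(out) <- c("power_curve", class(out))
  out
}

#' Plot a power curve
#'
#' Detection frequency against gene-wise total effect size.
#'
#' @param object A [power_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$effect, y = .data$detection)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "gene-wise total effect (sum of MAF x beta)",
                  y = "detection frequency",
                  title = "Power to identify a causal gene vs effect size") +
    ggplot2::theme_minimal()
}

#' Plot top-gene selection counts
#'
#' Bar chart of the combined selection counts of the top-ranked genes for
#' one trait and method.
#'
#' @param screen A [screen_all()] result.
#' @param trait,method Which screen to plot.
#' @param n Number of genes, default 10.
#' @return A ggplot.
#' @export
plot_top_genes <- function(screen, trait, method, n = 10) {
  tg <- top_genes(screen, trait, method, n)
  ggplot2::ggplot(tg, ggplot2::aes(x = stats::reorder(.data$gene, .data$average_count),
                                   y = .data$average_count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "average selection count across partition sizes",
                  title = paste0("Top genes: ", trait, ", ", method)) +
    ggplot2::theme_minimal()
}
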