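# small simulated cohort shared across screen tests
small_world <- function(seed = 101, n_replicates = 4) {
  model <- sim_model(n_individuals = 120, n_genes = 6,
                     mean_snps_per_gene = 4, n_replicates = n_replicates,
                     case_fraction = 0.3, seed = seed)
  geno <- simulate_genotypes(model)
  sim <- simulate_phenotypes(geno, model)
  list(model = model, geno = geno, pheno = sim$phenotypes)
}

test_that("vectorised statistic kernels equal the reference tests", {
  set.seed(55)
  n <- 80
  lab <- sample(1:5, n, replace = TRUE)
  sizes <- tabulate(lab, 5)
  Y <- cbind(rnorm(n), rnorm(n) + lab / 3, rbinom(n, 1, 0.4))
  fa <- ipwclust:::fast_anova(Y, lab, sizes)
  fp <- ipwclust:::fast_pr(Y, lab, sizes)
  for (j in 1:3) {
    ref <- anova_test(Y[, j], lab)
    expect_equal(fa$statistic[j], ref$statistic)
    expect_equal(fa$p_value[j], ref$p_value)
    expect_equal(fp$statistic[j], partition_retention_i(Y[, j], lab)$i_score)
  }
  Yb <- cbind(rbinom(n, 1, 0.3), rbinom(n, 1, 0.5))
  fc <- ipwclust:::fast_chisq(Yb, lab, sizes)
  for (j in 1:2) {
    ref <- chisq_test(Yb[, j], lab)
    expect_equal(fc$statistic[j], ref$statistic)
    expect_equal(fc$p_value[j], ref$p_value)
  }
})

test_that("screen_gene runs the full per-gene pipeline", {
  w <- small_world()
  cfg <- screen_config(ks = c(3, 5), seed = 2)
  res <- screen_gene(w$geno, "GENE001", w$pheno, cfg)
  # anova + pr for 4 traits, chisq for Affected only, times 2 ks
  expect_equal(nrow(res), (4 * 2 + 1) * 2)
  expect_setequal(unique(res$method),
                  c("anova", "chisq", "partition_retention"))
  expect_true(all(res$p_value[res$method != "partition_retention"] >= 0))
  expect_true(all(is.na(res$p_value[res$method == "partition_retention"])))
  expect_true(all(res$statistic[res$method == "partition_retention"] >= 0))
})

test_that("a gene with few distinct genotype profiles still screens", {
  # one common SNP: at most 3 distinct profiles, cut at k = 5 is legal
  dos <- matrix(rbinom(40, 2, 0.4), ncol = 1)
  g <- make_geno(asplit(dos, 1), genes = "G1")
  ph <- tibble::tibble(replicate = 1L,
                       individual_id = g$individual_ids,
                       Q1 = rnorm(40), Q2 = rnorm(40), Q4 = rnorm(40),
                       Affected = rbinom(40, 1, 0.3))
  res <- screen_gene(g, "G1", ph, screen_config(ks = 5, traits = "Q1",
                                                methods = "anova"))
  expect_equal(nrow(res), 1)
  expect_true(is.finite(res$statistic))
  sc <- screen_all(g, ipwclust:::validate_pheno_set(ph),
                   screen_config(ks = 5, traits = "Q1", methods = "anova"))
  expect_equal(nrow(sc$capped), 1)
})

test_that("screen_all counts selections consistently with screen_gene", {
  w <- small_world()
  cfg <- screen_config(ks = c(4, 6), traits = c("Q1", "Affected"), seed = 9)
  sc <- screen_all(w$geno, w$pheno, cfg)
  expect_s3_class(sc, "gene_screen")
  expect_true(all(sc$counts$count >= 0 & sc$counts$count <= sc$n_replicates))
  # summary averages the per-k counts
  one <- sc$counts |>
    dplyr::filter(gene == "GENE002", trait == "Q1", method == "anova")
  avg <- sc$summary |>
    dplyr::filter(gene == "GENE002", trait == "Q1", method == "anova")
  expect_equal(avg$average_count, mean(one$count))
  # statistics behind the counts match the single-gene path, replicate 1
  sg <- screen_gene(w$geno, "GENE003", w$pheno, cfg)
  Y <- matrix(w$pheno$Q1[w$pheno$replicate == 1], ncol = 1)
  idx <- gene_index(w$geno)
  lab <- ipwclust:::gene_partitions(w$geno, idx$GENE003, c(4, 6))
  f1 <- ipwclust:::fast_anova(Y, lab[, 1], tabulate(lab[, 1], 4))
  expect_equal(
    sg$statistic[sg$trait == "Q1" & sg$method == "anova" & sg$k == 4],
    f1$statistic[1])
  # tidy/glance accessors return the tables
  expect_identical(tidy(sc), sc$counts)
  expect_identical(glance(sc), sc$summary)
})

test_that("the screen is deterministic and writes byte-identical tables", {
  w <- small_world()
  cfg <- screen_config(ks = c(4, 5), traits = c("Q1", "Affected"), seed = 77)
  s1 <- screen_all(w$geno, w$pheno, cfg)
  s2 <- screen_all(w$geno, w$pheno, cfg)
  expect_identical(s1$counts, s2$counts)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_results_tsv(s1$counts, p1)
  write_results_tsv(s2$counts, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("nonsynonymous-only results match all-SNP results when no SNP is synonymous", {
  w <- small_world(seed = 202)
  geno <- w$geno
  geno$snps$synonymous <- FALSE
  cfg_all <- screen_config(ks = 4:5, traits = "Q1", methods = "anova",
                           snp_filter = "all")
  cfg_ns <- screen_config(ks = 4:5, traits = "Q1", methods = "anova",
                          snp_filter = "nonsynonymous")
  s_all <- screen_all(geno, w$pheno, cfg_all)
  s_ns <- screen_all(geno, w$pheno, cfg_ns)
  expect_equal(s_all$counts, s_ns$counts)
})

test_that("genes filtered to zero SNPs are skipped with a record", {
  w <- small_world(seed = 303)
  geno <- w$geno
  # make one gene entirely synonymous
  geno$snps$synonymous[geno$snps$gene == "GENE001"] <- TRUE
  geno$snps$synonymous[geno$snps$gene != "GENE001"] <- FALSE
  sc <- screen_all(geno, w$pheno,
                   screen_config(ks = 4, traits = "Q1", methods = "anova",
                                 snp_filter = "nonsynonymous"))
  expect_true("GENE001" %in% sc$skipped)
  expect_false("GENE001" %in% sc$counts$gene)
})

test_that("gene effect sizes sum MAF times beta over causal SNPs", {
  # two causal SNPs with sample MAF 0.01 and 0.005 (n = 100)
  dos1 <- integer(100); dos1[1] <- 2L   # maf 0.01
  dos2 <- integer(100); dos2[2] <- 1L   # maf 0.005
  dos3 <- rbinom(100, 2, 0.3)
  g <- make_geno(asplit(cbind(dos1, dos2, dos3), 1),
                 genes = c("G1", "G1", "G2"))
  truth <- tibble::tibble(snp_id = c("s01", "s02"), trait = "Q1",
                          beta = c(1, 2))
  eff <- gene_effect_sizes(truth, g, trait = "Q1")
  expect_equal(eff$total_effect[eff$gene == "G1"], 0.01 * 1 + 0.005 * 2)
  # genes with no causal SNP have total effect 0
  expect_equal(eff$total_effect[eff$gene == "G2"], 0)
  # negative effects contribute negatively
  eff_neg <- gene_effect_sizes(
    tibble::tibble(snp_id = "s01", trait = "Q1", beta = -3), g)
  expect_equal(eff_neg$total_effect[eff_neg$gene == "G1"], -0.03)
  expect_error(gene_effect_sizes(
    tibble::tibble(snp_id = "sXX", trait = "Q1", beta = 1), g), "unknown")
})

test_that("power curves join detection frequencies with effects", {
  w <- small_world()
  cfg <- screen_config(ks = 4, traits = "Q1", methods = "anova")
  sc <- screen_all(w$geno, w$pheno, cfg)
  eff <- gene_effect_sizes(NULL, w$geno)
  pc <- power_curve(sc, eff, trait = "Q1", method = "anova")
  expect_s3_class(pc, "power_curve")
  expect_equal(nrow(pc), sc$n_genes)
  expect_true(all(diff(pc$effect) >= 0))
  expect_true(all(pc$detection >= 0 & pc$detection <= 1))
  # single gene: one-row table
  pc1 <- power_curve(sc, eff[eff$gene == "GENE001", ], "Q1", "anova")
  expect_equal(nrow(pc1), 1)
  plt <- autoplot(pc)
  expect_s3_class(plt, "ggplot")
})

test_that("top_genes ranks by combined selection count", {
  w <- small_world()
  sc <- screen_all(w$geno, w$pheno,
                   screen_config(ks = 4:5, traits = "Q1",
                                 methods = "partition_retention"))
  tg <- top_genes(sc, "Q1", "partition_retention", n = 3)
  expect_lte(nrow(tg), 3)
  expect_true(all(diff(tg$average_count) <= 0))
  plt <- plot_top_genes(sc, "Q1", "partition_retention")
  expect_s3_class(plt, "ggplot")
})
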