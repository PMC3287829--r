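#' Mini-exome simulation model
#'
#' Describes a synthetic mini-exome in the shape of the GAW17 unrelated-
#' individuals data: 697 individuals, a rare-variant-heavy MAF spectrum
#' (74% of SNPs below 1%), genes of varying SNP counts, three quantitative
#' traits plus a dichotomous affection status with 209 cases out of 697,
#' and 200 phenotype replicates simulated over one fixed genotype matrix.
#'
#' @param n_individuals Number of individuals, default 697.
#' @param n_genes Number of genes, default 100.
#' @param mean_snps_per_gene Mean SNPs per gene; counts are drawn as
#'   `1 + Poisson(mean - 1)`. Default 7.6 (about 24,487 SNPs over 3,205
#'   genes in the mini-exome being emulated).
#' @param rare_fraction Fraction of SNPs drawn from the rare stratum
#'   (MAF < 0.01), default 0.74.
#' @param case_fraction Target fraction of affected individuals, default
#'   `209/697`.
#' @param n_replicates Phenotype replicates over the fixed genotypes,
#'   default 200.
#' @param trait_sd Standard deviation of the additive trait noise, default 1.
#' @param liability_trait Trait whose value (plus independent noise of sd
#'   `liability_sd`) is thresholded to produce `Affected`, default `"Q1"`.
#' @param liability_sd Noise sd of the liability, default 1.
#' @param synonymous_prob Probability a SNP is flagged synonymous,
#'   default 0.5.
#' @param causal Optional causal map: tibble with columns `snp_id`, `trait`,
#'   `beta` (one row per causal SNP-trait pair); `NULL` for an all-null
#'   model.
#' @param seed Integer seed; every draw the simulator makes flows from it.
#' @return A `sim_model` list of the above settings.
#' @export
sim_model <- function(n_individuals = 697, n_genes = 100,
                      mean_snps_per_gene = 7.6, rare_fraction = 0.74,
                      case_fraction = 209 / 697, n_replicates = 200,
                      trait_sd = 1, liability_trait = "Q1", liability_sd = 1,
                      synonymous_prob = 0.5, causal = NULL, seed = 1L) {
  if (n_individuals < 2) abort("need at least 2 individuals")
  if (rare_fraction < 0 || rare_fraction > 1) abort("rare_fraction must lie in [0, 1]")
  if (case_fraction <= 0 || case_fraction >= 1) abort("case_fraction must lie in (0, 1)")
  if (!is.null(causal)) {
    causal <- tibble::as_tibble(causal)
    stopifnot(all(c("snp_id", "trait", "beta") %in% names(causal)))
    if (any(!is.finite(causal$beta))) abort("causal effects must be finite")
  }
  structure(list(
    n_individuals = as.integer(n_individuals), n_genes = as.integer(n_genes),
    mean_snps_per_gene = mean_snps_per_gene, rare_fraction = rare_fraction,
    case_fraction = case_fraction, n_replicates = as.integer(n_replicates),
    trait_sd = trait_sd, liability_trait = liability_trait,
    liability_sd = liability_sd, synonymous_prob = synonymous_prob,
    causal = causal, seed = as.integer(seed)
  ), class = "sim_model")
}

#' Simulate a fixed genotype matrix with a rare-variant-heavy MAF spectrum
#'
#' Per SNP, a stratum is chosen first — rare with probability
#' `rare_fraction`, common otherwise — and a true MAF is drawn within it:
#' log-uniform on `[1/(2n), 0.01)` for rare SNPs (populating the very-rare
#' tail below 0.5%), uniform on `[0.01, 0.5]` for common ones. Genotypes
#' are drawn under Hardy-Weinberg equilibrium independently across SNPs
#' (no linkage disequilibrium, no admixture). A draw whose realised sample
#' MAF leaves its stratum — a monomorphic column, a rare SNP observed at
#' 1% or more, a common SNP observed below 1% — is redrawn (20 rounds, then
#' dropped), so the *observed* MAF spectrum matches `rare_fraction` by
#' construction, which is how the emulated data report their spectrum.
#' Each SNP is assigned to a gene (genes laid round-robin on chromosomes
#' 1-22) and a Bernoulli synonymous flag.
#'
#' @param model A [sim_model()].
#' @return A [geno_matrix()] with full annotation; the stored `maf` is the
#'   sample MAF, as used by the similarity scores, and the generating truth
#'   is kept in an extra `true_maf` column.
#' @export
simulate_genotypes <- function(model) {
  stopifnot(inherits(model, "sim_model"))
  n <- model$n_individuals
  withr_seed(model$seed, {
    snps_per_gene <- 1L + stats::rpois(model$n_genes,
                                       max(model$mean_snps_per_gene - 1, 0))
    m <- sum(snps_per_gene)
    gene_of <- rep(seq_len(model$n_genes), snps_per_gene)
    lo <- log(1 / (2 * n))
    rare <- runif(m) < model$rare_fraction
    draw_maf <- function(rare_j) {
      ifelse(rare_j, exp(runif(length(rare_j), lo, log(0.01))),
             runif(length(rare_j), 0.01, 0.5))
    }
    in_stratum <- function(dos_j, rare_j) {
      f <- colMeans(dos_j) / 2
      f <- pmin(f, 1 - f)
      ifelse(rare_j, f > 0 & f < 0.01, f >= 0.01)
    }
    p <- draw_maf(rare)
    dos <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
    bad <- !in_stratum(dos, rare)
    for (tries in seq_len(20)) {
      if (!any(bad)) break
      p[bad] <- draw_maf(rare[bad])
      dos[, bad] <- rbinom(n * sum(bad), 2L, rep(p[bad], each = n))
      bad <- !in_stratum(dos, rare)
    }
    if (any(bad)) {
      dos <- dos[, !bad, drop = FALSE]
      gene_of <- gene_of[!bad]
      p <- p[!bad]
    }
    snp_in_gene <- stats::ave(gene_of, gene_of, FUN = seq_along)
    colnames(dos) <- sprintf("G%03d_S%02d", gene_of, snp_in_gene)
    rownames(dos) <- sprintf("ind%04d", seq_len(n))
    geno <- geno_matrix(dos)
    geno$snps$gene <- sprintf("GENE%03d", gene_of)
    geno$snps$chromosome <- as.character((gene_of - 1L) %% 22L + 1L)
    geno$snps$synonymous <- runif(ncol(dos)) < model$synonymous_prob
    geno$snps$true_maf <- p
    geno
  })
}

#' Simulate replicated phenotypes over fixed genotypes
#'
#' Quantitative traits follow a linear additive model,
#' `Q_t = sum_i beta_it * dosage_i + Normal(0, trait_sd)`, with effects taken
#' from the model's causal map (zero for all other SNPs). `Affected` is a
#' liability-threshold dichotomisation: the designated liability trait plus
#' independent noise is thresholded at its `(1 - case_fraction)` sample
#' quantile, giving exactly `round(case_fraction * n)` cases in every
#' replicate. Genotypes are held fixed; only the noise is redrawn across
#' replicates.
#'
#' @param geno A [geno_matrix()], typically from [simulate_genotypes()].
#' @param model The [sim_model()] holding the causal map and noise levels.
#' @return List with `phenotypes` (a `pheno_set` tibble: `replicate`,
#'   `individual_id`, `Q1`, `Q2`, `Q4`, `Affected`) and `truth` (tibble
#'   `snp_id`, `gene`, `trait`, `beta`, `maf` for every causal SNP-trait
#'   pair).
#' @export
simulate_phenotypes <- function(geno, model) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(model, "sim_model"))
  n <- nrow(geno$dosages)
  traits <- c("Q1", "Q2", "Q4")
  causal <- model$causal
  if (!is.null(causal)) {
    unknown <- setdiff(causal$snp_id, geno$snps$snp_id)
    if (length(unknown)) {
      abort(paste0("causal SNP id(s) not in genotypes: ",
                   paste(head(unknown, 3), collapse = ", ")))
    }
  }
  signal <- matrix(0, n, length(traits), dimnames = list(NULL, traits))
  if (!is.null(causal)) {
    for (tr in intersect(traits, unique(causal$trait))) {
      cc <- causal[causal$trait == tr, ]
      cols <- match(cc$snp_id, geno$snps$snp_id)
      signal[, tr] <- geno$dosages[, cols, drop = FALSE] %*% cc$beta
    }
  }
  n_cases <- round(model$case_fraction * n)
  reps <- withr_seed(model$seed + 1L, lapply(seq_len(model$n_replicates), function(r) {
    q <- signal + matrix(rnorm(n * 3, 0, model$trait_sd), n, 3)
    colnames(q) <- traits
    liab <- q[, model$liability_trait] + rnorm(n, 0, model$liability_sd)
    affected <- as.integer(rank(liab, ties.method = "first") > n - n_cases)
    tibble::tibble(replicate = as.integer(r),
                   individual_id = geno$individual_ids,
                   Q1 = q[, "Q1"], Q2 = q[, "Q2"], Q4 = q[, "Q4"],
                   Affected = affected)
  }))
  phenotypes <- validate_pheno_set(dplyr::bind_rows(reps))
  truth <- if (is.null(causal)) {
    tibble::tibble(snp_id = character(), gene = character(),
                   trait = character(), beta = numeric(), maf = numeric())
  } else {
    idx <- match(causal$snp_id, geno$snps$snp_id)
    tibble::tibble(snp_id = causal$snp_id, gene = geno$snps$gene[idx],
                   trait = causal$trait, beta = causal$beta,
                   maf = geno$snps$maf[idx])
  }
  list(phenotypes = phenotypes, truth = truth)
}

#' Causal map assigning one effect size per gene
#'
#' Convenience constructor for [sim_model()]'s `causal` argument: every SNP
#' of each listed gene receives the gene's `beta` on the given trait, so
#' the gene-wise total effect is `beta * sum of its SNP MAFs`.
#'
#' @param geno A [geno_matrix()].
#' @param genes Character vector of gene ids.
#' @param beta Numeric effect sizes, recycled along `genes`.
#' @param trait Trait name, default `"Q1"`.
#' @return Tibble with columns `snp_id`, `trait`, `beta`.
#' @export
causal_map_for_genes <- function(geno, genes, beta, trait = "Q1") {
  beta <- rep_len(beta, length(genes))
  purrr::map2_dfr(genes, beta, function(g, b) {
    snps <- geno$snps$snp_id[!is.na(geno$snps$gene) & geno$snps$gene == g]
    if (!length(snps)) abort(paste0("gene not found in genotypes: ", g))
    tibble::tibble(snp_id = snps, trait = trait, beta = b)
  })
}

#' Planted single-rare-variant fixture
#'
#' Builds one gene in which a designated set of carriers shares one copy of
#' a rare variant, against a background of common SNPs with random
#' Hardy-Weinberg genotypes. Because the inverse-probability weighting makes
#' the shared rare allele dominate the common-SNP noise, the screen's
#' partitioning is expected to isolate the carriers in a single element —
#' the behaviour the method is designed to exploit.
#'
#' @param n_carriers Number of heterozygous carriers (at least 1).
#' @param n_individuals Cohort size, default 697.
#' @param n_common Number of common background SNPs, default 4.
#' @param common_maf_range MAF range of the background SNPs, default
#'   `c(0.05, 0.45)`.
#' @param seed Integer seed.
#' @return List with `genotypes` (a single-gene [geno_matrix()], gene
#'   `"PLANTED"`), `carriers` (integer indices of the carriers) and
#'   `rare_snp` (its SNP id).
#' @export
planted_cluster_fixture <- function(n_carriers, n_individuals = 697,
                                    n_common = 4,
                                    common_maf_range = c(0.05, 0.45),
                                    seed = 1L) {
  if (n_carriers < 1) abort("need at least 1 carrier")
  if (n_carriers >= n_individuals) abort("carriers must be fewer than individuals")
  withr_seed(seed, {
    carriers <- sort(sample.int(n_individuals, n_carriers))
    rare <- integer(n_individuals)
    rare[carriers] <- 1L
    p_common <- runif(n_common, common_maf_range[1], common_maf_range[2])
    common <- vapply(p_common, function(p) rbinom(n_individuals, 2L, p),
                     integer(n_individuals))
    dos <- cbind(rare, common)
    colnames(dos) <- c("PLANTED_S01", sprintf("PLANTED_S%02d", seq_len(n_common) + 1L))
    rownames(dos) <- sprintf("ind%04d", seq_len(n_individuals))
    geno <- geno_matrix(dos)
    geno$snps$gene <- "PLANTED"
    geno$snps$chromosome <- "1"
    geno$snps$synonymous <- FALSE
    list(genotypes = geno, carriers = carriers, rare_snp = "PLANTED_S01")
  })
}
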