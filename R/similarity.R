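#' Inverse-probability weighted allelic similarity score
#'
#' Scores a pair of alleles at a biallelic SNP with minor allele `a` at
#' frequency `p`. A match on allele `x` scores `1/p_x - 1` (so sharing the
#' rare allele is worth far more than sharing the common one) and a mismatch
#' scores `-1`. Drawing both alleles independently at the population
#' frequencies gives the score expectation exactly 0:
#' `p^2 (1/p - 1) + (1-p)^2 (1/(1-p) - 1) - 2 p (1-p) = 0`.
#'
#' @param x,y Alleles, `"a"` (minor) or `"A"` (major); vectorised.
#' @param p Minor allele frequency, in `(0, 0.5]`.
#' @return Numeric score(s).
#' @export
#' @examples
#' allelic_score("a", "a", 0.01) # 99
#' allelic_score("a", "A", 0.5)  # -1
allelic_score <- function(x, y, p) {
  check_maf(p)
  if (!all(c(x, y) %in% c("a", "A"))) abort('alleles must be "a" or "A"')
  px <- ifelse(x == "a", p, 1 - p)
  ifelse(x == y, 1 / px - 1, -1)
}

#' Allelic score table
#'
#' @param p Minor allele frequency in `(0, 0.5]`.
#' @return A 2x2 numeric matrix of scores indexed by alleles `a`, `A`.
#' @export
allele_score_table <- function(p) {
  check_maf(p)
  al <- c("a", "A")
  outer(al, al, function(x, y) allelic_score(x, y, p)) |>
    structure(dimnames = list(al, al))
}

#' Inverse-probability weighted genotypic similarity score
#'
#' Generalises [allelic_score()] to unordered genotypes: the score of two
#' genotypes is half the sum of the allelic scores over the four cross-pairs
#' of their alleles. For example, `aa` versus `aA` has one `(a, a)` match
#' and one `(a, A)` mismatch, so the rare-allele match dominates and the
#' pair scores high. Under Hardy-Weinberg genotype frequencies for two
#' independent individuals the expectation is exactly 0.
#'
#' @param g1,g2 Minor-allele dosages in `{0, 1, 2}`; vectorised.
#' @param p Minor allele frequency, in `(0, 0.5]`; recycled.
#' @return Numeric score(s).
#' @export
#' @examples
#' genotype_score(2, 1, 0.01) # 1/p - 2 = 98
#' genotype_score(0, 0, 0.5)  # 2
genotype_score <- function(g1, g2, p) {
  check_maf(p)
  if (!all(g1 %in% 0:2) || !all(g2 %in% 0:2)) abort("dosages must be 0, 1 or 2")
  sa <- (1 - p) / p       # (a, a) match
  sA <- p / (1 - p)       # (A, A) match
  0.5 * (g1 * g2 * sa + (2 - g1) * (2 - g2) * sA -
           (g1 * (2 - g2) + (2 - g1) * g2))
}

#' Genotypic score table
#'
#' @param p Minor allele frequency in `(0, 0.5]`.
#' @return A 3x3 symmetric numeric matrix of scores indexed by dosage
#'   (`"0"`, `"1"`, `"2"` copies of the minor allele).
#' @export
genotype_score_table <- function(p) {
  g <- 0:2
  outer(g, g, genotype_score, p = p) |>
    structure(dimnames = list(as.character(g), as.character(g)))
}

check_maf <- function(p) {
  if (any(p <= 0) || any(p >= 1)) {
    abort("minor allele frequency must lie strictly inside (0, 1)")
  }
  if (any(p > 0.5)) {
    abort("p must be the minor allele frequency (at most 0.5)")
  }
  invisible(p)
}

#' Gene-level pairwise similarity of individuals
#'
#' For a gene, the similarity of individuals i and j is the sum over the
#' gene's SNPs of the per-SNP genotypic scores,
#' `sim(i, j) = sum_k sim(i, j; k)`, each SNP scored at its own sample MAF.
#' The diagonal holds self-similarity; clustering uses only the
#' off-diagonal values after the distance transform.
#'
#' @param geno A [geno_matrix()].
#' @param gene Gene id to look up in the annotation (used when `columns` is
#'   `NULL`).
#' @param columns Integer column indices of the SNPs to use; overrides
#'   `gene`.
#' @return A `gene_similarity`: an n x n symmetric numeric matrix with
#'   attributes `gene` and `columns`.
#' @export
gene_similarity <- function(geno, gene = NULL, columns = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (is.null(columns)) {
    if (is.null(gene)) abort("supply either `gene` or `columns`")
    columns <- which(geno$snps$gene %in% gene & geno$snps$maf > 0)
  }
  if (!length(columns)) abort("no usable SNP columns for this gene")
  if (any(geno$snps$maf[columns] <= 0)) {
    abort("monomorphic SNP in `columns`: score undefined at MAF 0")
  }
  n <- nrow(geno$dosages)
  S <- matrix(0, n, n)
  for (k in columns) {
    tab <- genotype_score_table(geno$snps$maf[k])
    gk <- geno$dosages[, k] + 1L
    S <- S + tab[gk, gk, drop = FALSE]
  }
  dimnames(S) <- list(geno$individual_ids, geno$individual_ids)
  structure(S, gene = if (is.null(gene)) NA_character_ else gene,
            columns = columns, class = c("gene_similarity", "matrix", "array"))
}

#' Convert gene similarity to a bounded distance
#'
#' Applies the monotone-decreasing transform `d(i, j) = exp(-sim(i, j) / a)`
#' with normalising constant `a = max(1, max|sim|/20)` taken over the
#' off-diagonal entries, so that every distance at the gene is bounded by
#' `e^20`. The diagonal is set to 0.
#'
#' @param sim A [gene_similarity()] matrix (any symmetric matrix accepted).
#' @return A `gene_distance`: an n x n symmetric nonnegative matrix with
#'   zero diagonal and attributes `gene` and `normalizer`.
#' @export
similarity_to_distance <- function(sim) {
  S <- unclass(sim)
  n <- nrow(S)
  if (n < 2) abort("need at least 2 individuals")
  off <- abs(S[upper.tri(S) | lower.tri(S)])
  a <- max(1, max(off) / 20)
  D <- exp(-S / a)
  diag(D) <- 0
  structure(D, gene = attr(sim, "gene", exact = TRUE), normalizer = a,
            class = c("gene_distance", "matrix", "array"))
}

#' Write a per-gene distance matrix to TSV
#'
#' Square table with individual ids as header and first column, for use by
#' external clustering tools.
#'
#' @param dist A [similarity_to_distance()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dist, path) {
  tab <- tibble::as_tibble(unclass(dist), .name_repair = "minimal")
  tab <- dplyr::bind_cols(tibble::tibble(individual_id = rownames(dist)), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
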