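# Small genotype fixtures built in code.

# n individuals x m SNPs from explicit dosage rows
make_geno <- function(dosage_rows, genes = NULL, synonymous = NULL) {
  dos <- do.call(rbind, dosage_rows)
  rownames(dos) <- sprintf("i%02d", seq_len(nrow(dos)))
  colnames(dos) <- sprintf("s%02d", seq_len(ncol(dos)))
  g <- geno_matrix(dos)
  if (!is.null(genes)) g$snps$gene <- genes
  if (!is.null(synonymous)) g$snps$synonymous <- synonymous
  g
}

# 4 individuals x 2 SNPs with dosages chosen so both columns have the target
# sample MAFs 0.125 and 0.375 (hand-checkable similarity sums)
geno_4x2 <- function() {
  make_geno(list(c(1L, 2L), c(0L, 1L), c(0L, 0L), c(0L, 0L)),
            genes = c("G1", "G1"))
}

# brute-force genotypic score: half the sum of allelic scores over the four
# allele cross-pairs; independent of the closed-form used in the package
brute_genotype_score <- function(g1, g2, p) {
  a1 <- c(rep("a", g1), rep("A", 2 - g1))
  a2 <- c(rep("a", g2), rep("A", 2 - g2))
  0.5 * sum(outer(a1, a2, function(x, y) allelic_score(x, y, p)))
}

# brute-force gene similarity by per-pair summation
brute_gene_similarity <- function(geno, cols) {
  n <- nrow(geno$dosages)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    S[i, j] <- sum(vapply(cols, function(k) {
      brute_genotype_score(geno$dosages[i, k], geno$dosages[j, k],
                           geno$snps$maf[k])
    }, numeric(1)))
  }
  S
}

# agreement of two label vectors up to relabelling
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# y and labels realising a given 2 x k table (row 1 = y == 0)
yl_from_table <- function(tab) {
  k <- ncol(tab)
  y <- integer(0)
  labels <- integer(0)
  for (j in seq_len(k)) {
    y <- c(y, rep(0L, tab[1, j]), rep(1L, tab[2, j]))
    labels <- c(labels, rep(j, sum(tab[, j])))
  }
  list(y = y, labels = labels)
}
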