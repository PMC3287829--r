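#' Genotype matrix container
#'
#' A `geno_matrix` bundles a complete individuals-by-SNPs minor-allele dosage
#' matrix with per-SNP metadata. Dosages count copies of the *minor* allele
#' (0, 1 or 2); columns whose raw alternate-allele frequency exceeds 0.5 are
#' folded at construction so that every stored column has minor allele
#' frequency (MAF) at most 0.5. Missing genotypes are rejected: the screen
#' requires complete inputs.
#'
#' @param dosages Integer matrix, individuals in rows, SNPs in columns,
#'   entries in `{0, 1, 2}`. Row names are individual ids, column names SNP
#'   ids (generated when absent).
#' @param annotation Optional tibble with columns `snp_id`, `gene`,
#'   `chromosome`, `synonymous`, merged onto the SNP table (see
#'   [set_annotation()]).
#' @param fold Should columns with alternate-allele frequency above 0.5 be
#'   folded to minor-allele orientation? Default `TRUE`. Frequencies of
#'   exactly 0.5 are left as given.
#'
#' @return An object of class `geno_matrix`: a list with elements `dosages`
#'   (integer matrix), `individual_ids` (character) and `snps` (tibble with
#'   `snp_id`, `gene`, `chromosome`, `synonymous`, `maf`).
#' @export
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 2L, 0L), 2, 2,
#'   dimnames = list(c("i1", "i2"), c("s1", "s2"))))
#' g$snps$maf
geno_matrix <- function(dosages, annotation = NULL, fold = TRUE) {
  dosages <- as.matrix(dosages)
  if (anyNA(dosages)) {
    abort("missing genotype calls are not allowed; inputs must be complete")
  }
  if (!all(dosages %in% c(0, 1, 2))) {
    bad <- which(!(dosages %in% c(0, 1, 2)))[1]
    abort(sprintf("dosage entries must be 0, 1 or 2 (first offending value: %s)",
                  format(dosages[bad])))
  }
  storage.mode(dosages) <- "integer"
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("ind%03d", seq_len(nrow(dosages)))
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("snp%04d", seq_len(ncol(dosages)))
  }
  if (anyDuplicated(colnames(dosages))) {
    abort("SNP ids must be unique")
  }
  n <- nrow(dosages)
  if (fold && n > 0) {
    af <- colMeans(dosages) / 2
    flip <- af > 0.5
    if (any(flip)) dosages[, flip] <- 2L - dosages[, flip]
  }
  maf <- if (n > 0) colMeans(dosages) / 2 else rep(NA_real_, ncol(dosages))
  snps <- tibble::tibble(
    snp_id = colnames(dosages),
    gene = NA_character_,
    chromosome = NA_character_,
    synonymous = NA,
    maf = as.numeric(maf)
  )
  out <- structure(
    list(dosages = dosages, individual_ids = rownames(dosages), snps = snps),
    class = "geno_matrix"
  )
  if (!is.null(annotation)) out <- set_annotation(out, annotation)
  out
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  ng <- dplyr::n_distinct(x$snps$gene[!is.na(x$snps$gene)])
  cat(sprintf("  annotated genes: %d; MAF range: %s\n", ng,
              paste(signif(range(x$snps$maf), 3), collapse = " - ")))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Attach a SNP annotation to a genotype matrix
#'
#' Merges an annotation table (as returned by [read_snp_annotation()]) onto
#' the SNP metadata of a `geno_matrix`. Annotated SNPs absent from the
#' genotypes are reported and dropped; genotype SNPs without annotation keep
#' `NA` gene and are excluded from [gene_index()].
#'
#' @param geno A [geno_matrix()].
#' @param annotation Tibble with columns `snp_id`, `gene`, `chromosome`,
#'   `synonymous`.
#' @return `geno` with its `snps` tibble updated.
#' @export
set_annotation <- function(geno, annotation) {
  stopifnot(inherits(geno, "geno_matrix"))
  annotation <- tibble::as_tibble(annotation)
  req <- c("snp_id", "gene", "chromosome", "synonymous")
  missing_cols <- setdiff(req, names(annotation))
  if (length(missing_cols)) {
    abort(paste0("annotation is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(annotation$snp_id)) {
    abort("duplicate snp_id in annotation")
  }
  dropped <- setdiff(annotation$snp_id, geno$snps$snp_id)
  if (length(dropped)) {
    inform(sprintf("%d annotated SNP(s) absent from genotypes were dropped (e.g. %s)",
                   length(dropped), dropped[1]))
  }
  empty <- !is.na(annotation$gene) & annotation$gene == ""
  if (any(empty)) {
    warn(sprintf("%d SNP(s) with empty gene field excluded from gene grouping",
                 sum(empty)))
    annotation$gene[empty] <- NA_character_
  }
  ann <- annotation[match(geno$snps$snp_id, annotation$snp_id), ]
  geno$snps$gene <- as.character(ann$gene)
  geno$snps$chromosome <- as.character(ann$chromosome)
  geno$snps$synonymous <- as.logical(ann$synonymous)
  geno
}

#' Group SNP columns by gene
#'
#' Builds the gene-to-columns index used by the per-gene screen. Monomorphic
#' SNPs (sample MAF of 0) carry no similarity information — an allele with
#' frequency 0 makes the inverse-probability score undefined — and are
#' dropped with a warning. Under `snp_filter = "nonsynonymous"` only SNPs
#' explicitly flagged nonsynonymous (`synonymous == FALSE`) are kept;
#' SNPs with an absent flag are excluded from that analysis.
#'
#' @param geno A [geno_matrix()] with gene annotation.
#' @param snp_filter `"all"` or `"nonsynonymous"`.
#' @return Named list mapping gene id to the integer column indices of its
#'   SNPs, in input column order. Genes left without SNPs are not stored.
#' @export
gene_index <- function(geno, snp_filter = c("all", "nonsynonymous")) {
  stopifnot(inherits(geno, "geno_matrix"))
  snp_filter <- match.arg(snp_filter)
  keep <- !is.na(geno$snps$gene)
  mono <- keep & geno$snps$maf == 0
  if (any(mono)) {
    warn(sprintf("%d monomorphic SNP(s) dropped from gene index", sum(mono)))
    keep <- keep & !mono
  }
  if (snp_filter == "nonsynonymous") {
    keep <- keep & !is.na(geno$snps$synonymous) & !geno$snps$synonymous
  }
  idx <- which(keep)
  if (!length(idx)) return(structure(list(), names = character()))
  split(idx, factor(geno$snps$gene[idx], levels = unique(geno$snps$gene[idx])))
}

#' SNP metadata as a tibble
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return The per-SNP metadata tibble (`snp_id`, `gene`, `chromosome`,
#'   `synonymous`, `maf`).
#' @export
tidy.geno_matrix <- function(x, ...) x$snps
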