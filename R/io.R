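#' Read a genotype matrix from VCF or a dosage table
#'
#' Two formats are supported: a VCF v4.x with biallelic records and a `GT`
#' field, or a tab-separated dosage matrix whose header row holds SNP ids and
#' whose first column holds individual ids. In both cases dosages are
#' re-expressed as minor-allele counts: a column whose alternate-allele
#' frequency exceeds 0.5 is folded (`2 - dosage`). Multiallelic records and
#' missing calls are rejected — the method requires complete biallelic
#' genotypes.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"vcf"` or `"matrix"`.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "matrix"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_matrix(path)
}

read_genotypes_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- ids
  geno_matrix(mat)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (!all(bi)) {
    pos <- paste(v@fix[!bi, "CHROM"], v@fix[!bi, "POS"], sep = ":")
    abort(paste0("multiallelic VCF record(s) at ", paste(head(pos, 3), collapse = ", ")))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) abort("VCF has no GT field")
  alleles <- gsub("\\|", "/", gt)
  if (anyNA(alleles) || any(grepl("\\.", alleles))) {
    abort("missing genotype call in VCF; inputs must be complete (imputation is out of scope)")
  }
  dos <- matrix(0L, nrow = ncol(alleles), ncol = nrow(alleles))
  parts <- strsplit(as.vector(alleles), "/", fixed = TRUE)
  counts <- vapply(parts, function(a) sum(a == "1"), integer(1))
  if (any(!vapply(parts, function(a) all(a %in% c("0", "1")), logical(1)))) {
    abort("VCF GT alleles must be 0 or 1 (biallelic)")
  }
  # extract.gt returns variants x samples; transpose to individuals x SNPs
  dos <- t(matrix(counts, nrow = nrow(alleles), ncol = ncol(alleles)))
  rownames(dos) <- colnames(alleles)
  ids <- v@fix[, "ID"]
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(v@fix[blank, "CHROM"], "_", v@fix[blank, "POS"])
  colnames(dos) <- ids
  geno <- geno_matrix(dos)
  geno$snps$chromosome <- as.character(v@fix[, "CHROM"])
  geno
}

#' Write a genotype matrix
#'
#' Emits either the dosage-table format or a minimal VCF (placeholder
#' REF/ALT alleles, `GT` only, the minor allele written as ALT) that
#' [read_genotypes()] reads back unchanged.
#'
#' @param geno A [geno_matrix()].
#' @param path Output path.
#' @param format `"matrix"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("matrix", "vcf")) {
  stopifnot(inherits(geno, "geno_matrix"))
  format <- match.arg(format)
  if (format == "matrix") {
    tab <- tibble::as_tibble(geno$dosages, .name_repair = "minimal")
    tab <- dplyr::bind_cols(tibble::tibble(individual_id = geno$individual_ids), tab)
    readr::write_tsv(tab, path, progress = FALSE)
  } else {
    chrom <- geno$snps$chromosome
    chrom[is.na(chrom)] <- "1"
    gt_codes <- c("0/0", "0/1", "1/1")
    body <- vapply(seq_len(ncol(geno$dosages)), function(k) {
      paste(c(chrom[k], k, geno$snps$snp_id[k], "A", "C", ".", "PASS", ".", "GT",
              gt_codes[geno$dosages[, k] + 1L]), collapse = "\t")
    }, character(1))
    header <- c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", geno$individual_ids), collapse = "\t")
    )
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Read a SNP annotation table
#'
#' Expects a TSV with columns `snp_id`, `gene`, `chromosome`, `synonymous`
#' (`true`/`false`/`NA`). Duplicate SNP ids are rejected; empty gene fields
#' are treated as unannotated.
#'
#' @param path Path to the TSV.
#' @return Tibble with the four columns, `synonymous` logical.
#' @export
read_snp_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(),
    gene = readr::col_character(),
    chromosome = readr::col_character(),
    synonymous = readr::col_logical()
  ), progress = FALSE)
  if (anyDuplicated(ann$snp_id)) abort("duplicate snp_id in annotation file")
  ann
}

#' Write a SNP annotation table
#'
#' @param geno A [geno_matrix()] whose `snps` tibble is written.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_annotation <- function(geno, path) {
  readr::write_tsv(geno$snps[, c("snp_id", "gene", "chromosome", "synonymous")],
                   path, progress = FALSE)
  invisible(path)
}

#' Read phenotype replicates
#'
#' Each file is a TSV with columns `individual_id`, `Q1`, `Q2`, `Q4`,
#' `Affected` over the same individuals; file order defines replicate order.
#' `Q1`, `Q2`, `Q4` are quantitative traits; `Affected` is dichotomous and
#' must lie in `{0, 1}`.
#'
#' @param paths Character vector of file paths, one per replicate.
#' @return A `pheno_set`: a tibble with columns `replicate`,
#'   `individual_id`, `Q1`, `Q2`, `Q4`, `Affected`.
#' @export
read_phenotypes <- function(paths) {
  reps <- purrr::imap(paths, function(p, i) {
    tab <- readr::read_tsv(p, col_types = readr::cols(
      individual_id = readr::col_character(),
      .default = readr::col_double()
    ), progress = FALSE)
    req <- c("individual_id", "Q1", "Q2", "Q4", "Affected")
    if (!all(req %in% names(tab))) {
      abort(paste0("phenotype file ", p, " lacks required columns"))
    }
    dplyr::mutate(tab[req], replicate = as.integer(i), .before = 1)
  })
  out <- dplyr::bind_rows(reps)
  validate_pheno_set(out)
}

validate_pheno_set <- function(x) {
  if (!all(x$Affected %in% c(0, 1))) {
    abort("Affected status must be 0 or 1")
  }
  first <- x$individual_id[x$replicate == x$replicate[1]]
  same <- all(vapply(split(x$individual_id, x$replicate),
                     function(ids) identical(ids, first), logical(1)))
  if (!same) abort("all replicates must share individual ids and ordering")
  class(x) <- c("pheno_set", class(tibble::tibble()))
  x
}

#' Align phenotype replicates to a genotype matrix
#'
#' Reorders every replicate to the genotype individual ordering; any
#' mismatch in the individual sets is an error listing the symmetric
#' difference.
#'
#' @param pheno A `pheno_set` from [read_phenotypes()] or
#'   [simulate_phenotypes()].
#' @param geno A [geno_matrix()].
#' @return The reordered `pheno_set`.
#' @export
align_phenotypes <- function(pheno, geno) {
  ids <- unique(pheno$individual_id)
  extra <- setdiff(ids, geno$individual_ids)
  missing <- setdiff(geno$individual_ids, ids)
  if (length(extra) || length(missing)) {
    abort(sprintf(
      "individuals mismatch genotypes: %d only in phenotypes (e.g. %s), %d only in genotypes (e.g. %s)",
      length(extra), paste(head(extra, 2), collapse = ","),
      length(missing), paste(head(missing, 2), collapse = ",")))
  }
  out <- dplyr::arrange(pheno, .data$replicate,
                        match(.data$individual_id, geno$individual_ids))
  validate_pheno_set(tibble::as_tibble(out))
}

#' Write phenotype replicates
#'
#' One TSV per replicate, named `<prefix>_rep<index>.tsv`, in the exact
#' format [read_phenotypes()] reads.
#'
#' @param pheno A `pheno_set`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix, default `"pheno"`.
#' @return Character vector of paths, invisibly.
#' @export
write_phenotypes <- function(pheno, dir, prefix = "pheno") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  reps <- sort(unique(pheno$replicate))
  paths <- vapply(reps, function(r) {
    p <- file.path(dir, sprintf("%s_rep%03d.tsv", prefix, r))
    readr::write_tsv(dplyr::select(dplyr::filter(pheno, .data$replicate == r),
                                   -"replicate"), p, progress = FALSE)
    p
  }, character(1))
  invisible(paths)
}
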