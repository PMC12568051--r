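#' Genotype matrix container
#'
#' Holds an individuals-by-SNPs matrix of allele-count codes together with the
#' SNP map and the per-SNP frequency of the counted allele. Codes count copies
#' of the counted allele (PLINK allele 1), so each entry is 0, 1, 2 or `NA`.
#'
#' @param codes Numeric matrix, individuals in rows and SNPs in columns, with
#'   values in `{0, 1, 2, NA}`. Row and column names are used as individual and
#'   SNP identifiers; defaults are generated when absent.
#' @param map Optional tibble/data frame with columns `snp_id`, `chrom`, `pos`
#'   giving the SNP map. Defaults to chromosome 0 and positions `1:n_snps`.
#' @param allow_imputed Accept fractional codes in `[0, 2]` (mean-imputed
#'   panels, see [qc_filter()]) instead of the strict `{0, 1, 2, NA}` set.
#'
#' @return An object of class `genotype_matrix`: a list with elements `codes`,
#'   `map` (tibble), `individual_ids`, `snp_ids` and `allele_freq` (frequency
#'   of the counted allele, computed from non-missing codes).
#' @export
genotype_matrix <- function(codes, map = NULL, allow_imputed = FALSE) {
  if (!is.matrix(codes)) abort("`codes` must be a matrix.")
  bad <- if (allow_imputed) {
    which(!is.na(codes) & (codes < 0 | codes > 2))
  } else {
    which(!(is.na(codes) | codes == 0 | codes == 1 | codes == 2))
  }
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(codes)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(codes)) + 1L
    abort(sprintf(
      "Genotype codes must be 0, 1, 2 or NA; found %s at row %d, column %d.",
      format(codes[bad[1]]), i, j
    ))
  }
  if (is.null(rownames(codes))) {
    rownames(codes) <- sprintf("ind_%04d", seq_len(nrow(codes)))
  }
  if (is.null(colnames(codes))) {
    colnames(codes) <- sprintf("snp_%05d", seq_len(ncol(codes)))
  }
  if (anyDuplicated(rownames(codes))) abort("Individual ids must be unique.")
  if (anyDuplicated(colnames(codes))) abort("SNP ids must be unique.")
  if (is.null(map)) {
    map <- tibble(
      snp_id = colnames(codes),
      chrom = 0L,
      pos = seq_len(ncol(codes))
    )
  } else {
    map <- as_tibble(map)
    if (!all(c("snp_id", "chrom", "pos") %in% names(map))) {
      abort("`map` must have columns snp_id, chrom, pos.")
    }
    if (nrow(map) != ncol(codes) || !identical(as.character(map$snp_id), colnames(codes))) {
      abort("`map` rows must match the SNP columns of `codes` (same ids, same order).")
    }
  }
  structure(
    list(
      codes = codes,
      map = map,
      individual_ids = rownames(codes),
      snp_ids = colnames(codes),
      allele_freq = allele_frequencies(codes)
    ),
    class = "genotype_matrix"
  )
}

# Frequency of the counted allele from non-missing codes.
allele_frequencies <- function(codes) {
  colMeans(codes, na.rm = TRUE) / 2
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d individuals x %d SNPs; %.2f%% missing\n",
    nrow(x$codes), ncol(x$codes), 100 * mean(is.na(x$codes))
  ))
  cat(sprintf(
    "  counted-allele frequency: min %.3f, median %.3f, max %.3f\n",
    min(x$allele_freq), stats::median(x$allele_freq), max(x$allele_freq)
  ))
  invisible(x)
}

#' @exportS3Method base::dim
dim.genotype_matrix <- function(x) dim(x$codes)

#' Subset a genotype panel
#'
#' @param geno A [genotype_matrix()].
#' @param individuals,snps Character ids or indices; `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the selection. Allele frequencies
#'   are recomputed on the retained individuals.
#' @export
subset_genotypes <- function(geno, individuals = NULL, snps = NULL) {
  check_genotype_matrix(geno)
  ii <- if (is.null(individuals)) seq_len(nrow(geno$codes)) else individuals
  jj <- if (is.null(snps)) seq_len(ncol(geno$codes)) else snps
  codes <- geno$codes[ii, jj, drop = FALSE]
  map <- geno$map[match(colnames(codes), geno$map$snp_id), ]
  genotype_matrix(codes, map, allow_imputed = TRUE)
}

check_genotype_matrix <- function(geno) {
  if (!inherits(geno, "genotype_matrix")) {
    abort("Expected a `genotype_matrix` (see `genotype_matrix()`).")
  }
  invisible(geno)
}
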