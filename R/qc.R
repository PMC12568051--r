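#' Quality-control a genotype panel
#'
#' Filters a panel in three ordered passes: individuals below the individual
#' call-rate threshold are removed first, then SNPs below the SNP call-rate
#' threshold, then SNPs whose minor allele frequency (computed on the retained
#' individuals) falls below `maf_min`. Remaining missing codes are imputed to
#' the SNP mean code `2 * p` so that downstream relationship matrices can be
#' built on complete data; imputation leaves the counted-allele frequency of
#' every SNP unchanged. Retained ids keep their input order.
#'
#' @param geno A [genotype_matrix()].
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param snp_callrate_min,ind_callrate_min Minimum fraction of non-missing
#'   codes per SNP / per individual (defaults 0.90).
#' @param impute Impute remaining missing codes to `2 * p` (default `TRUE`).
#'
#' @return A list with elements `genotypes` (the filtered, imputed panel) and
#'   `report`, a one-row tibble with columns `n_snps_in`, `n_snps_out`,
#'   `n_removed_maf`, `n_removed_callrate`, `n_individuals_removed`,
#'   `n_imputed` and the thresholds used.
#' @export
qc_filter <- function(geno, maf_min = 0.01, snp_callrate_min = 0.90,
                      ind_callrate_min = 0.90, impute = TRUE) {
  check_genotype_matrix(geno)
  for (th in c(maf_min, snp_callrate_min, ind_callrate_min)) {
    stopifnot_scalar_number(th, "threshold", 0, 1)
  }
  codes <- geno$codes
  n_snps_in <- ncol(codes)

  ind_cr <- rowMeans(!is.na(codes))
  keep_ind <- ind_cr >= ind_callrate_min
  n_ind_removed <- sum(!keep_ind)
  codes <- codes[keep_ind, , drop = FALSE]
  if (nrow(codes) == 0L) abort("All individuals removed by call-rate filter.")

  snp_cr <- colMeans(!is.na(codes))
  keep_cr <- snp_cr >= snp_callrate_min
  n_removed_callrate <- sum(!keep_cr)
  codes <- codes[, keep_cr, drop = FALSE]

  p <- allele_frequencies(codes)
  maf <- pmin(p, 1 - p)
  keep_maf <- !is.na(maf) & maf >= maf_min
  n_removed_maf <- sum(!keep_maf)
  codes <- codes[, keep_maf, drop = FALSE]
  if (ncol(codes) == 0L) abort("All SNPs removed by QC; empty panel.")

  n_imputed <- 0L
  if (impute && anyNA(codes)) {
    p_kept <- allele_frequencies(codes)
    miss <- which(is.na(codes))
    n_imputed <- length(miss)
    codes[miss] <- (2 * p_kept)[((miss - 1L) %/% nrow(codes)) + 1L]
  }

  out <- genotype_matrix(codes, geno$map[match(colnames(codes), geno$map$snp_id), ],
                         allow_imputed = TRUE)
  report <- tibble(
    n_snps_in = n_snps_in,
    n_snps_out = ncol(codes),
    n_removed_callrate = n_removed_callrate,
    n_removed_maf = n_removed_maf,
    n_individuals_removed = n_ind_removed,
    n_imputed = n_imputed,
    maf_min = maf_min,
    snp_callrate_min = snp_callrate_min,
    ind_callrate_min = ind_callrate_min
  )
  list(genotypes = out, report = report)
}
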