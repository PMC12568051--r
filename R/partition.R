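#' Split a SNP panel into prior and residual sets by GWAS p-value
#'
#' Sorts SNPs by ascending p-value (ties broken by chromosome, position, then
#' SNP id, so the split is invariant to input row order) and places the first
#' `floor(fraction * n)` SNPs in the prior set; the rest form the residual
#' set. The two sets are a disjoint cover of the panel.
#'
#' @param pvals Tibble with columns `snp_id`, `chrom`, `pos`, `p_value`
#'   (one row per panel SNP; see [run_ad_gwas()]).
#' @param fraction Prior fraction in (0, 1), e.g. 0.05 for the top 5%.
#' @return An object of class `snp_partition`: a list with `fraction`,
#'   `prior_ids`, `residual_ids`, `n_prior`, `n_residual`.
#' @export
select_top_fraction <- function(pvals, fraction) {
  pvals <- as_tibble(pvals)
  req <- c("snp_id", "chrom", "pos", "p_value")
  if (!all(req %in% names(pvals))) {
    abort("`pvals` must have columns snp_id, chrom, pos, p_value.")
  }
  stopifnot_scalar_number(fraction, "fraction", 0, 1)
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must lie strictly in (0, 1).")
  if (anyDuplicated(pvals$snp_id)) abort("`pvals` must have one row per SNP.")
  bad <- pvals$snp_id[is.na(pvals$p_value) | pvals$p_value <= 0 | pvals$p_value > 1]
  if (length(bad)) {
    abort(sprintf(
      "%d SNPs have missing or invalid p-values: %s%s",
      length(bad), paste(head(bad, 5), collapse = ", "),
      if (length(bad) > 5) ", ..." else ""
    ))
  }
  n <- nrow(pvals)
  ord <- order(pvals$p_value, pvals$chrom, pvals$pos, pvals$snp_id)
  n_prior <- floor(fraction * n)
  prior_ids <- pvals$snp_id[ord[seq_len(n_prior)]]
  residual_ids <- pvals$snp_id[ord[setdiff(seq_len(n), seq_len(n_prior))]]
  structure(
    list(
      fraction = fraction,
      prior_ids = prior_ids,
      residual_ids = residual_ids,
      n_prior = n_prior,
      n_residual = n - n_prior
    ),
    class = "snp_partition"
  )
}

#' @exportS3Method base::print
print.snp_partition <- function(x, ...) {
  cat(sprintf(
    "<snp_partition> top %.0f%%: %d prior SNPs, %d residual SNPs\n",
    100 * x$fraction, x$n_prior, x$n_residual
  ))
  invisible(x)
}
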