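#' Minimal additive + dominance single-SNP association scan
#'
#' Produces per-SNP p-values for ranking markers. Records are first adjusted
#' for the fixed-effect factors by ordinary least squares, the adjusted values
#' are averaged per individual, and each SNP is then tested by comparing the
#' linear model with an additive allele-count covariate (0/1/2) and a
#' heterozygosity indicator (0/1) against the intercept-only model with an
#' F-test. The scan ignores relatedness; it exists to supply ordered
#' p-values for self-contained runs, and externally supplied GWAS results can
#' be used instead anywhere a p-value table is accepted.
#'
#' @param geno A [genotype_matrix()] with complete codes.
#' @param pheno Record-level phenotype tibble (see [simulate_phenotypes()]).
#' @param covariates Character vector of fixed-effect factor columns in
#'   `pheno` to adjust for (default flock, sex, age, year; factors with a
#'   single observed level are dropped).
#' @return A tibble with columns `snp_id`, `chrom`, `pos`, `p_value`.
#'   Monomorphic SNPs receive `p_value = 1` and are flagged in the
#'   `monomorphic` column.
#' @export
run_ad_gwas <- function(geno, pheno,
                        covariates = c("flock", "sex", "age", "year")) {
  check_genotype_matrix(geno)
  pheno <- as_tibble(pheno)
  missing_ind <- setdiff(unique(pheno$individual_id), geno$individual_ids)
  if (length(missing_ind)) {
    abort(sprintf(
      "%d phenotyped individuals are not genotyped (e.g. %s).",
      length(missing_ind), missing_ind[1]
    ))
  }
  covariates <- intersect(covariates, names(pheno))
  covariates <- covariates[vapply(
    covariates,
    function(f) length(unique(pheno[[f]])) > 1L, logical(1)
  )]
  if (length(covariates)) {
    fml <- as.formula(paste("value ~", paste(covariates, collapse = " + ")))
    adj <- stats::residuals(lm(fml, data = pheno))
  } else {
    adj <- pheno$value - mean(pheno$value)
  }
  ybar <- tapply(adj, pheno$individual_id, mean)
  idx <- match(names(ybar), geno$individual_ids)
  y <- as.numeric(ybar)
  y <- y - mean(y)
  n <- length(y)
  rss0 <- sum(y^2)

  codes <- geno$codes[idx, , drop = FALSE]
  if (anyNA(codes)) abort("Codes contain missing values; impute first (see qc_filter()).")
  m <- ncol(codes)
  pvals <- numeric(m)
  mono <- logical(m)
  for (j in seq_len(m)) {
    x <- codes[, j]
    if (var(x) == 0) {
      pvals[j] <- 1
      mono[j] <- TRUE
      next
    }
    h <- (x == 1) * 1
    fit <- stats::lm.fit(cbind(1, x, h), y)
    df1 <- fit$rank - 1L
    df2 <- n - fit$rank
    rss1 <- sum(fit$residuals^2)
    if (df1 < 1L || df2 < 1L || rss1 <= 0) {
      pvals[j] <- 1
      next
    }
    f_stat <- ((rss0 - rss1) / df1) / (rss1 / df2)
    pvals[j] <- pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  tibble(
    snp_id = geno$snp_ids,
    chrom = geno$map$chrom,
    pos = geno$map$pos,
    p_value = pvals,
    monomorphic = mono
  )
}
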