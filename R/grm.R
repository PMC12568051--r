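#' Relationship matrix container
#'
#' @param values Symmetric numeric matrix with individual ids as dimnames.
#' @param kind `"additive"`, `"dominance"` or `"combined"`.
#' @param scaling_denominator The scaling constant used
#'   (`2 * sum(p q)` for additive, `4 * sum(p^2 q^2)` for dominance;
#'   `NA` for combined matrices).
#' @param source_snp_set Character vector of SNP ids the matrix was built
#'   from, or `"all"`.
#' @param ridge_added Total ridge added to the diagonal so far.
#' @return A `relationship_matrix` object.
#' @export
relationship_matrix <- function(values, kind, scaling_denominator = NA_real_,
                                source_snp_set = "all", ridge_added = 0) {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    abort("`values` must be a square matrix.")
  }
  if (is.null(rownames(values))) abort("`values` must carry individual ids as dimnames.")
  if (!is_symmetric_tol(values)) abort("`values` must be symmetric.")
  kind <- match.arg(kind, c("additive", "dominance", "combined"))
  structure(
    list(
      individual_ids = rownames(values),
      values = values,
      kind = kind,
      scaling_denominator = scaling_denominator,
      ridge_added = ridge_added,
      source_snp_set = source_snp_set
    ),
    class = "relationship_matrix"
  )
}

#' @exportS3Method base::print
print.relationship_matrix <- function(x, ...) {
  cat(sprintf(
    "<relationship_matrix> %s, %d individuals, mean diagonal %.3f, ridge %.2e\n",
    x$kind, nrow(x$values), mean(diag(x$values)), x$ridge_added
  ))
  invisible(x)
}

#' @exportS3Method base::dim
dim.relationship_matrix <- function(x) dim(x$values)

resolve_snp_set <- function(geno, snp_set) {
  if (is.null(snp_set)) {
    return(seq_len(ncol(geno$codes)))
  }
  if (is.character(snp_set)) {
    idx <- match(snp_set, geno$snp_ids)
    if (anyNA(idx)) {
      abort(sprintf(
        "SNP set contains ids not on the panel (e.g. %s).",
        snp_set[which(is.na(idx))[1]]
      ))
    }
    idx
  } else {
    as.integer(snp_set)
  }
}

#' Build the additive genomic relationship matrix
#'
#' VanRaden-style additive matrix: allele-count codes are centered columnwise
#' by twice the counted-allele frequency (`Z = M - 2p`) and the matrix is
#' `Z Z' / (2 * sum_j p_j q_j)`, with the sum (and the frequencies) taken over
#' the SNPs used. Frequencies are the observed frequencies on the full sample
#' stored in `geno`, regardless of `snp_set`.
#'
#' @param geno A [genotype_matrix()] with complete (imputed) codes.
#' @param snp_set SNP ids or indices to build from; `NULL` = whole panel.
#' @return A `relationship_matrix` of kind `"additive"`.
#' @export
build_additive_grm <- function(geno, snp_set = NULL) {
  check_genotype_matrix(geno)
  idx <- resolve_snp_set(geno, snp_set)
  if (length(idx) == 0L) abort("`snp_set` is empty.")
  codes <- geno$codes[, idx, drop = FALSE]
  if (anyNA(codes)) abort("Codes contain missing values; impute first (see qc_filter()).")
  p <- geno$allele_freq[idx]
  q <- 1 - p
  denom <- 2 * sum(p * q)
  if (denom <= .Machine$double.eps) {
    abort("All selected SNPs are monomorphic: zero scaling denominator.")
  }
  z <- sweep(codes, 2L, 2 * p, "-")
  g <- tcrossprod(z) / denom
  relationship_matrix(
    g, "additive",
    scaling_denominator = denom,
    source_snp_set = if (is.null(snp_set)) "all" else geno$snp_ids[idx]
  )
}

#' Build the dominance genomic relationship matrix
#'
#' Heterozygosity coding: each SNP contributes an indicator (1 for
#' heterozygotes, 0 for homozygotes) centered columnwise by `2 p_j q_j`
#' (its Hardy-Weinberg expectation), and the matrix is
#' `V V' / (4 * sum_j p_j^2 q_j^2)`. `center = "observed"` instead centers by
#' the observed heterozygote frequency (pure indicator parameterisation);
#' the default follows the hybrid coding conventional in goat/sheep
#' dominance GBLUP analyses.
#'
#' @inheritParams build_additive_grm
#' @param center `"2pq"` (default) or `"observed"`.
#' @return A `relationship_matrix` of kind `"dominance"`.
#' @export
build_dominance_grm <- function(geno, snp_set = NULL, center = c("2pq", "observed")) {
  check_genotype_matrix(geno)
  center <- match.arg(center)
  idx <- resolve_snp_set(geno, snp_set)
  if (length(idx) == 0L) abort("`snp_set` is empty.")
  codes <- geno$codes[, idx, drop = FALSE]
  if (anyNA(codes)) abort("Codes contain missing values; impute first (see qc_filter()).")
  p <- geno$allele_freq[idx]
  q <- 1 - p
  denom <- 4 * sum(p^2 * q^2)
  if (denom <= .Machine$double.eps) {
    abort("All selected SNPs are monomorphic: zero scaling denominator.")
  }
  het <- (codes == 1) * 1
  ctr <- if (center == "2pq") 2 * p * q else colMeans(het)
  v <- sweep(het, 2L, ctr, "-")
  d <- tcrossprod(v) / denom
  relationship_matrix(
    d, "dominance",
    scaling_denominator = denom,
    source_snp_set = if (is.null(snp_set)) "all" else geno$snp_ids[idx]
  )
}

#' Convex combination of two relationship matrices
#'
#' `tau * A + (1 - tau) * B`, the weighted trait-specific matrix of the
#' GBLUP-GA method when `A` is built from the prior marker set and `B` from
#' the residual set.
#'
#' @param A,B `relationship_matrix` objects over the same individuals (same
#'   order) and of the same kind.
#' @param tau Weight in \[0, 1\].
#' @return A `relationship_matrix` of kind `"combined"` (attribute `tau`
#'   records the weight).
#' @export
combine_matrices <- function(A, B, tau) {
  if (!inherits(A, "relationship_matrix") || !inherits(B, "relationship_matrix")) {
    abort("`A` and `B` must be relationship matrices.")
  }
  stopifnot_scalar_number(tau, "tau", 0, 1)
  if (!identical(A$individual_ids, B$individual_ids)) {
    abort("Individual ids of `A` and `B` differ; matrices are not aligned.")
  }
  out <- relationship_matrix(
    tau * A$values + (1 - tau) * B$values,
    "combined",
    scaling_denominator = NA_real_,
    source_snp_set = "combined",
    ridge_added = tau * A$ridge_added + (1 - tau) * B$ridge_added
  )
  attr(out, "tau") <- tau
  out
}

#' Ridge-regularise a relationship matrix
#'
#' Adds `ridge_factor * mean(diag)` to the diagonal so that matrices built
#' from SNP subsets (rank-deficient when the subset is smaller than the
#' number of individuals) can be inverted in the mixed-model equations. The
#' shift moves every eigenvalue up by exactly the amount added.
#'
#' @param A A `relationship_matrix`.
#' @param ridge_factor Non-negative scalar (default `1e-6`).
#' @return `A` with the ridge added and `ridge_added` updated.
#' @export
regularize <- function(A, ridge_factor = 1e-6) {
  if (!inherits(A, "relationship_matrix")) abort("`A` must be a relationship matrix.")
  stopifnot_scalar_number(ridge_factor, "ridge_factor", 0)
  if (ridge_factor == 0) {
    return(A)
  }
  add <- ridge_factor * mean(diag(A$values))
  A$values <- A$values + diag(add, nrow(A$values))
  A$ridge_added <- A$ridge_added + add
  A
}
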