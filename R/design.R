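#' Model specification for the repeated-record animal model
#'
#' @param trait Name of the response column metadata (label only).
#' @param fixed_factors Ordered character vector of fixed-effect factor
#'   columns in the phenotype table.
#' @param include_dominance Fit an individual dominance effect with a
#'   dominance relationship matrix.
#' @param include_permanent_env Fit an individual permanent-environment
#'   effect (identity covariance).
#' @return A `model_spec` list.
#' @export
model_spec <- function(trait = "trait",
                       fixed_factors = c("flock", "age", "sex", "year"),
                       include_dominance = TRUE,
                       include_permanent_env = TRUE) {
  structure(
    list(
      trait = trait,
      fixed_factors = fixed_factors,
      include_dominance = isTRUE(include_dominance),
      include_permanent_env = isTRUE(include_permanent_env)
    ),
    class = "model_spec"
  )
}

#' Build design matrices for the repeated-record animal model
#'
#' Constructs the response vector and incidence matrices of
#' `y = Xb + Zu + Wp + Vd + e`: `X` is the full-rank fixed-effect incidence
#' (intercept plus treatment-coded factors, first level dropped), and the
#' additive, permanent-environment and dominance terms share a single
#' records-by-individuals incidence `Z` (each record attaches to one
#' individual). `individual_order` fixes the column order of `Z` and may
#' include individuals without records (their columns are empty), which is how
#' validation individuals enter prediction.
#'
#' @param pheno Record-level tibble with a `value` column, an
#'   `individual_id` column and the factor columns named in `spec`.
#' @param spec A [model_spec()].
#' @param individual_order Character vector of individual ids covering at
#'   least every phenotyped individual.
#' @return A `design_set` list: `y`, `X` (dense), `Z` (sparse), `counts`
#'   (records per individual, in `individual_order`), `individual_order`,
#'   `xlev` (factor levels used), `spec`.
#' @export
build_design <- function(pheno, spec = model_spec(), individual_order = NULL) {
  pheno <- as_tibble(pheno)
  if (!all(c("individual_id", "value") %in% names(pheno))) {
    abort("`pheno` needs `individual_id` and `value` columns.")
  }
  factors <- intersect(spec$fixed_factors, names(pheno))
  miss <- setdiff(spec$fixed_factors, names(pheno))
  if (length(miss)) {
    abort(sprintf("Fixed factors not in `pheno`: %s", paste(miss, collapse = ", ")))
  }
  if (is.null(individual_order)) {
    individual_order <- unique(pheno$individual_id)
  }
  not_covered <- setdiff(pheno$individual_id, individual_order)
  if (length(not_covered)) {
    abort(sprintf(
      "`individual_order` is missing %d phenotyped individuals (e.g. %s).",
      length(not_covered), not_covered[1]
    ))
  }
  dat <- pheno
  # refit factor levels on the observed data; single-level factors drop out
  xlev <- list()
  keep <- character()
  for (f in factors) {
    fv <- factor(dat[[f]])
    dat[[f]] <- fv
    if (nlevels(fv) > 1L) {
      keep <- c(keep, f)
      xlev[[f]] <- levels(fv)
    }
  }
  fml <- if (length(keep)) {
    as.formula(paste("~", paste(keep, collapse = " + ")))
  } else {
    ~1
  }
  X <- model.matrix(fml, data = dat)
  # drop aliased columns (levels confounded across factors) to keep X full rank
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    X <- X[, sort(qx$pivot[seq_len(qx$rank)]), drop = FALSE]
  }
  j <- match(dat$individual_id, individual_order)
  Z <- Matrix::sparseMatrix(
    i = seq_len(nrow(dat)), j = j, x = 1,
    dims = c(nrow(dat), length(individual_order)),
    dimnames = list(NULL, individual_order)
  )
  counts <- tabulate(j, nbins = length(individual_order))
  structure(
    list(
      y = as.numeric(dat$value),
      X = X,
      Z = Z,
      counts = counts,
      individual_order = individual_order,
      formula = fml,
      xlev = xlev,
      spec = spec
    ),
    class = "design_set"
  )
}

#' @exportS3Method base::print
print.design_set <- function(x, ...) {
  cat(sprintf(
    "<design_set> %d records, %d fixed-effect columns, %d individuals (%d phenotyped)\n",
    length(x$y), ncol(x$X), length(x$individual_order), sum(x$counts > 0)
  ))
  invisible(x)
}
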