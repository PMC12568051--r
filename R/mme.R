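#' Solve the mixed-model equations
#'
#' Henderson's block system for the repeated-record animal model with an
#' additive genomic term, an optional permanent-environment term and an
#' optional dominance term. With variance ratios
#' `alpha1 = sigma_e2 / sigma_a2`, `alpha2 = sigma_e2 / sigma_p2`,
#' `alpha3 = sigma_e2 / sigma_d2`, the coefficient matrix stacks
#' `X'X`, `Z'Z + alpha1 G^-1`, `Z'Z + alpha2 I`, `Z'Z + alpha3 D^-1`
#' (and the corresponding cross blocks) against the right-hand side
#' `(X'y, Z'y, Z'y, Z'y)`. Terms excluded by the design's model spec are
#' dropped from the system. Individuals present in `G` but without records
#' still receive additive solutions (genomic prediction of unphenotyped
#' individuals).
#'
#' @param design A [build_design()] result.
#' @param G Additive `relationship_matrix` (invertible; see [regularize()]).
#' @param D Dominance `relationship_matrix` when the spec includes dominance.
#' @param vc A `reml_fit` (or list with `sigma_a2`, `sigma_p2`, `sigma_d2`,
#'   `sigma_e2`) supplying the variance components.
#' @return An object of class `mme_solution`: `b_hat` (fixed-effect level
#'   estimates, named by design column), `u_hat` (additive genomic values,
#'   the GEBVs, named by individual), `p_hat`, `d_hat` (or `NULL` when the
#'   term is absent), and `xlev`/`formula` carried from the design for
#'   prediction-time reuse.
#' @export
solve_mme <- function(design, G, D = NULL, vc) {
  if (!inherits(design, "design_set")) abort("`design` must come from build_design().")
  order <- design$individual_order
  Gm <- align_relationship(G, order, "G")
  has_p <- design$spec$include_permanent_env
  has_d <- design$spec$include_dominance
  if (has_d && is.null(D)) abort("Model includes dominance but `D` is missing.")
  Dm <- if (has_d) align_relationship(D, order, "D") else NULL

  se <- vc$sigma_e2
  sa <- vc$sigma_a2
  if (!is.finite(se) || se <= 0 || !is.finite(sa) || sa <= 0) {
    abort("`vc` must provide positive sigma_a2 and sigma_e2.")
  }
  alpha1 <- se / sa
  alpha2 <- if (has_p) se / vc$sigma_p2 else NULL
  alpha3 <- if (has_d) se / vc$sigma_d2 else NULL

  X <- design$X
  Z <- design$Z
  p <- ncol(X)
  q <- length(order)
  XtX <- crossprod(X)
  XtZ <- as.matrix(Matrix::crossprod(X, Z))
  ZtZ <- diag(design$counts, q)
  Xty <- crossprod(X, design$y)[, 1]
  Zty <- as.numeric(Matrix::crossprod(Z, design$y))

  Ginv <- tryCatch(
    chol2inv(chol(Gm)),
    error = function(e) abort("Additive (G) block is singular; regularize() it first.")
  )
  blocks <- list(X = p, u = q)
  if (has_p) blocks$p <- q
  if (has_d) blocks$d <- q
  dim_tot <- sum(unlist(blocks))
  C <- matrix(0, dim_tot, dim_tot)
  rhs <- numeric(dim_tot)
  off <- cumsum(c(0, unlist(blocks)))
  ix <- seq_len(p)
  iu <- off[2] + seq_len(q)
  C[ix, ix] <- XtX
  C[ix, iu] <- XtZ
  C[iu, ix] <- base::t(XtZ)
  C[iu, iu] <- ZtZ + alpha1 * Ginv
  rhs[ix] <- Xty
  rhs[iu] <- Zty
  nxt <- 3L
  ip <- id <- NULL
  if (has_p) {
    ip <- off[nxt] + seq_len(q)
    nxt <- nxt + 1L
    C[ix, ip] <- XtZ
    C[ip, ix] <- base::t(XtZ)
    C[iu, ip] <- ZtZ
    C[ip, iu] <- ZtZ
    C[ip, ip] <- ZtZ + diag(alpha2, q)
    rhs[ip] <- Zty
  }
  if (has_d) {
    Dinv <- tryCatch(
      chol2inv(chol(Dm)),
      error = function(e) abort("Dominance (D) block is singular; regularize() it first.")
    )
    id <- off[nxt] + seq_len(q)
    C[ix, id] <- XtZ
    C[id, ix] <- base::t(XtZ)
    C[iu, id] <- ZtZ
    C[id, iu] <- ZtZ
    if (has_p) {
      C[ip, id] <- ZtZ
      C[id, ip] <- ZtZ
    }
    C[id, id] <- ZtZ + alpha3 * Dinv
    rhs[id] <- Zty
  }

  sol <- tryCatch(
    solve(C, rhs),
    error = function(e) abort("Mixed-model coefficient matrix is singular.")
  )
  structure(
    list(
      b_hat = setNames(sol[ix], colnames(X)),
      u_hat = setNames(sol[iu], order),
      p_hat = if (has_p) setNames(sol[ip], order) else NULL,
      d_hat = if (has_d) setNames(sol[id], order) else NULL,
      alpha = c(
        alpha1 = alpha1,
        alpha2 = if (has_p) alpha2 else NA_real_,
        alpha3 = if (has_d) alpha3 else NA_real_
      ),
      xlev = design$xlev,
      formula = design$formula,
      spec = design$spec
    ),
    class = "mme_solution"
  )
}

#' @exportS3Method base::print
print.mme_solution <- function(x, ...) {
  cat(sprintf(
    "<mme_solution> %d fixed-effect levels, %d individuals%s%s\n",
    length(x$b_hat), length(x$u_hat),
    if (!is.null(x$p_hat)) ", permanent env" else "",
    if (!is.null(x$d_hat)) ", dominance" else ""
  ))
  invisible(x)
}

#' Genetic parameters from variance components
#'
#' Additive heritability `sigma_a2 / sigma_total2`, dominance heritability
#' `sigma_d2 / sigma_total2` and repeatability
#' `(sigma_a2 + sigma_d2 + sigma_p2) / sigma_total2`, where the total is the
#' sum of all four components. Absent (`NA`) components contribute zero. The
#' three ratios are invariant to a common rescaling of all components.
#'
#' @param vc A `reml_fit`, or any list/vector with elements `sigma_a2`,
#'   `sigma_d2`, `sigma_p2`, `sigma_e2` (missing or `NA` treated as zero).
#' @return A one-row tibble with `h2_additive`, `h2_dominance`,
#'   `repeatability`.
#' @export
genetic_parameters <- function(vc) {
  g <- function(nm) {
    v <- tryCatch(vc[[nm]], error = function(e) NULL)
    if (is.null(v) || is.na(v)) 0 else as.numeric(v)
  }
  sa <- g("sigma_a2")
  sd2 <- g("sigma_d2")
  sp <- g("sigma_p2")
  se <- g("sigma_e2")
  total <- sa + sd2 + sp + se
  if (total <= 0) abort("Total phenotypic variance must be positive.")
  tibble(
    h2_additive = sa / total,
    h2_dominance = sd2 / total,
    repeatability = (sa + sd2 + sp) / total
  )
}
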