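#' Prior-set share of the genetic variance
#'
#' The GBLUP-GA weight: the prior marker set's share of the total genetic
#' variance,
#' `tau = (sGa1 + sGd1) / (sGa1 + sGd1 + sGa2 + sGd2)`,
#' where the numerator holds the additive and dominance genetic variances
#' estimated with the prior-set matrices and the denominator adds those from
#' the residual-set fit. Dominance terms are omitted for additive-only
#' models by passing 0 (or `NA`).
#'
#' @param sigma_Ga1_2,sigma_Gd1_2 Additive and dominance genetic variances
#'   from the prior-set fit.
#' @param sigma_Ga2_2,sigma_Gd2_2 The same from the residual-set fit.
#' @return `tau` in \[0, 1\]. When all four variances are exactly zero the
#'   weight is undefined and 0.5 is returned with a warning.
#' @export
compute_tau <- function(sigma_Ga1_2, sigma_Gd1_2 = 0, sigma_Ga2_2 = 0,
                        sigma_Gd2_2 = 0) {
  v <- c(sigma_Ga1_2, sigma_Gd1_2, sigma_Ga2_2, sigma_Gd2_2)
  v[is.na(v)] <- 0
  if (any(v < 0)) abort("Genetic variances must be non-negative.")
  num <- v[1] + v[2]
  den <- sum(v)
  if (den == 0) {
    warn("All genetic variances are zero; tau is undefined and set to 0.5.")
    return(0.5)
  }
  num / den
}

#' Fit the two partition models and compute the weight tau
#'
#' Runs two independent REML fits with the full fixed-effect and
#' permanent-environment structure: fit 1 uses only the prior-set matrices
#' `(G1, D1)`, fit 2 only the residual-set matrices `(G2, D2)`. The genetic
#' variances of the two fits give the prior-information weight via
#' [compute_tau()]. Floor-pinned components enter the ratio at their floor
#' value. A non-converged fit is flagged but tau is still computed.
#'
#' @param design A [build_design()] result (full model structure).
#' @param G1,G2 Additive relationship matrices from the prior and residual
#'   SNP sets (regularised).
#' @param D1,D2 Dominance matrices for the two sets, or `NULL` for
#'   additive-only models.
#' @param options [reml_options()] passed to both fits.
#' @return An object of class `partition_variances`: `sigma_Ga1_2`,
#'   `sigma_Gd1_2`, `sigma_Ga2_2`, `sigma_Gd2_2`, `tau`, `converged`
#'   (both fits), and the two `reml_fit`s (`fit_prior`, `fit_residual`).
#' @export
fit_partition_models <- function(design, G1, G2, D1 = NULL, D2 = NULL,
                                 options = reml_options()) {
  has_d <- design$spec$include_dominance
  if (has_d && (is.null(D1) || is.null(D2))) {
    abort("Model includes dominance: both `D1` and `D2` are required.")
  }
  fit1 <- reml_estimate(design, G1, D1, options = options)
  fit2 <- reml_estimate(design, G2, D2, options = options)
  tau <- compute_tau(
    fit1$sigma_a2, if (has_d) fit1$sigma_d2 else 0,
    fit2$sigma_a2, if (has_d) fit2$sigma_d2 else 0
  )
  if (!fit1$converged || !fit2$converged) {
    warn("At least one partition fit did not converge; tau is flagged.")
  }
  structure(
    list(
      sigma_Ga1_2 = fit1$sigma_a2,
      sigma_Gd1_2 = if (has_d) fit1$sigma_d2 else NA_real_,
      sigma_Ga2_2 = fit2$sigma_a2,
      sigma_Gd2_2 = if (has_d) fit2$sigma_d2 else NA_real_,
      tau = tau,
      converged = fit1$converged && fit2$converged,
      fit_prior = fit1,
      fit_residual = fit2
    ),
    class = "partition_variances"
  )
}

#' @exportS3Method base::print
print.partition_variances <- function(x, ...) {
  cat(sprintf(
    "<partition_variances> tau = %.3f (prior additive %.4g, residual additive %.4g)%s\n",
    x$tau, x$sigma_Ga1_2, x$sigma_Ga2_2,
    if (!x$converged) "  [non-converged fit]" else ""
  ))
  invisible(x)
}

#' Build the weighted (trait-specific) relationship matrices
#'
#' `Gt = tau * G1 + (1 - tau) * G2`, and likewise `Dt` when dominance
#' matrices are supplied. This is the genetic-architecture matrix used by the
#' final GBLUP-GA prediction model.
#'
#' @param G1,G2 Prior- and residual-set additive matrices.
#' @param tau Weight in \[0, 1\] (see [compute_tau()]).
#' @param D1,D2 Optional dominance matrices.
#' @return A list with `Gt` and `Dt` (`NULL` when dominance is absent).
#' @export
build_weighted_set <- function(G1, G2, tau, D1 = NULL, D2 = NULL) {
  Gt <- combine_matrices(G1, G2, tau)
  Dt <- if (!is.null(D1) && !is.null(D2)) combine_matrices(D1, D2, tau) else NULL
  list(Gt = Gt, Dt = Dt)
}
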