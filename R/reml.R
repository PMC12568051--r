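#' Options for the REML variance-component estimator
#'
#' @param tol Convergence tolerance on the relative change in the restricted
#'   log-likelihood (default `1e-8`).
#' @param max_iter Maximum iterations (default 200).
#' @param floor_frac Variance floor as a fraction of the sample phenotypic
#'   variance (default `1e-8`); components are pinned at the floor rather
#'   than estimated negative.
#' @param init Optional named numeric vector of starting values
#'   (`sigma_a2`, `sigma_p2`, `sigma_d2`, `sigma_e2`).
#' @param verbose Print the log-likelihood trajectory.
#' @return A `reml_options` list.
#' @export
reml_options <- function(tol = 1e-8, max_iter = 200L, floor_frac = 1e-8,
                         init = NULL, verbose = FALSE) {
  structure(
    list(
      tol = tol, max_iter = as.integer(max_iter),
      floor_frac = floor_frac, init = init, verbose = isTRUE(verbose)
    ),
    class = "reml_options"
  )
}

# Evaluate the restricted log-likelihood (and optionally its score vector and
# average-information matrix) for the repeated-record animal model
#   y = Xb + Z(u + p + d) + e,
# u ~ N(0, G sa), p ~ N(0, I sp), d ~ N(0, D sd), e ~ N(0, I se).
# All three random terms share the record-to-individual incidence Z, so
# V = Z K Z' + se I with K = sa G + sp I + sd D, and every solve reduces to
# q x q via the Woodbury identity (q = number of individuals).
reml_eval <- function(theta, pre, derivs = TRUE) {
  fail <- list(ll = -Inf)
  sa <- theta[["sigma_a2"]]
  se <- theta[["sigma_e2"]]
  if (se <= 0 || sa < 0) return(fail)
  q <- pre$q
  n <- pre$n

  K <- sa * pre$G
  if (pre$has_p) diag(K) <- diag(K) + theta[["sigma_p2"]]
  if (pre$has_d) K <- K + theta[["sigma_d2"]] * pre$D
  cK <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(cK)) return(fail)
  Kinv <- chol2inv(cK)
  logdetK <- 2 * sum(log(diag(cK)))

  Sq <- Kinv
  diag(Sq) <- diag(Sq) + pre$counts / se
  cS <- tryCatch(chol(Sq), error = function(e) NULL)
  if (is.null(cS)) return(fail)
  A <- chol2inv(cS)
  logdetSq <- 2 * sum(log(diag(cS)))

  AZtX <- A %*% pre$ZtX
  AZty <- as.numeric(A %*% pre$Zty)
  B <- (pre$XtX - crossprod(pre$ZtX, AZtX) / se) / se
  XtViy <- (pre$Xty - crossprod(pre$ZtX, AZty) / se) / se
  ytViy <- (pre$yty - sum(pre$Zty * AZty) / se) / se
  cB <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(cB)) return(fail)
  Binv <- chol2inv(cB)
  logdetB <- 2 * sum(log(diag(cB)))
  bhat <- as.numeric(Binv %*% XtViy)
  yPy <- ytViy - sum(XtViy * bhat)

  ll <- -0.5 * (n * log(se) + logdetK + logdetSq + logdetB + yPy)
  if (!is.finite(ll)) return(fail)
  if (!derivs) return(list(ll = ll, bhat = bhat))

  Z <- pre$Z
  counts <- pre$counts
  ViY <- pre$y / se - as.numeric(Z %*% AZty) / se^2
  ViX <- pre$X / se - as.matrix(Z %*% AZtX) / se^2
  Py <- ViY - as.numeric(ViX %*% bhat)
  w <- as.numeric(Matrix::crossprod(Z, Py))

  # Z' P Z, the q x q projection core shared by all trace terms
  ZtViZ <- -(A * outer(counts, counts)) / se^2
  diag(ZtViZ) <- diag(ZtViZ) + counts / se
  ZtViX <- (pre$ZtX - (counts * AZtX) / se) / se
  Tq <- ZtViZ - ZtViX %*% tcrossprod(Binv, ZtViX)

  comp <- pre$components
  k <- length(comp)
  score <- numeric(k)
  quad <- numeric(k)
  Fmat <- matrix(0, n, k)
  trXX <- sum(Binv * crossprod(ViX))
  for (i in seq_len(k)) {
    ci <- comp[i]
    if (ci == "sigma_a2") {
      trPV <- sum(pre$G * Tq)
      quad[i] <- sum(w * (pre$G %*% w))
      Fmat[, i] <- as.numeric(Z %*% (pre$G %*% w))
    } else if (ci == "sigma_p2") {
      trPV <- sum(diag(Tq))
      quad[i] <- sum(w^2)
      Fmat[, i] <- as.numeric(Z %*% w)
    } else if (ci == "sigma_d2") {
      trPV <- sum(pre$D * Tq)
      quad[i] <- sum(w * (pre$D %*% w))
      Fmat[, i] <- as.numeric(Z %*% (pre$D %*% w))
    } else { # sigma_e2
      trPV <- n / se - sum(counts * diag(A)) / se^2 - trXX
      quad[i] <- sum(Py^2)
      Fmat[, i] <- Py
    }
    score[i] <- -0.5 * (trPV - quad[i])
  }
  ZtF <- as.matrix(Matrix::crossprod(Z, Fmat))
  ViF <- Fmat / se - as.matrix(Z %*% (A %*% ZtF)) / se^2
  PF <- ViF - ViX %*% (Binv %*% crossprod(ViX, Fmat))
  AI <- 0.5 * crossprod(Fmat, PF)
  AI <- (AI + base::t(AI)) / 2

  list(
    ll = ll, bhat = bhat, score = setNames(score, comp),
    quad = setNames(quad, comp), AI = AI
  )
}

align_relationship <- function(R, order, what) {
  if (is.null(R)) return(NULL)
  if (!inherits(R, "relationship_matrix")) {
    abort(sprintf("`%s` must be a relationship_matrix.", what))
  }
  if (identical(R$individual_ids, order)) return(R$values)
  idx <- match(order, R$individual_ids)
  if (anyNA(idx)) {
    abort(sprintf(
      "`%s` does not cover every individual in the design (missing e.g. %s).",
      what, order[which(is.na(idx))[1]]
    ))
  }
  R$values[idx, idx, drop = FALSE]
}

reml_precompute <- function(design, G, D) {
  order <- design$individual_order
  Gm <- align_relationship(G, order, "G")
  has_d <- design$spec$include_dominance
  if (has_d && is.null(D)) {
    abort("Model includes dominance but no dominance matrix `D` was given.")
  }
  Dm <- if (has_d) align_relationship(D, order, "D") else NULL
  has_p <- design$spec$include_permanent_env
  components <- c(
    "sigma_a2",
    if (has_p) "sigma_p2",
    if (has_d) "sigma_d2",
    "sigma_e2"
  )
  list(
    y = design$y, X = design$X, Z = design$Z, counts = design$counts,
    G = Gm, D = Dm, has_p = has_p, has_d = has_d,
    n = length(design$y), q = length(order), p = ncol(design$X),
    XtX = crossprod(design$X), Xty = crossprod(design$X, design$y)[, 1],
    ZtX = as.matrix(Matrix::crossprod(design$Z, design$X)),
    Zty = as.numeric(Matrix::crossprod(design$Z, design$y)),
    yty = sum(design$y^2),
    components = components
  )
}

#' Estimate variance components by average-information REML
#'
#' Maximises the restricted likelihood of the repeated-record animal model
#' over the included variance components (additive, optional permanent
#' environment, optional dominance, residual) using average-information
#' (quasi-Newton) updates with step halving and an expectation-maximisation
#' fallback when an AI step fails or would decrease the likelihood.
#' Components are floored at `floor_frac` times the sample phenotypic
#' variance; a component sitting at the floor with a negative score is pinned
#' there and excluded from the update. Every accepted step increases the
#' restricted log-likelihood.
#'
#' Relationship matrices destined for small SNP subsets are rank-deficient;
#' pass them through [regularize()] first.
#'
#' @param design A [build_design()] result.
#' @param G Additive `relationship_matrix` covering the design's individuals.
#' @param D Dominance `relationship_matrix`, required when the model spec
#'   includes dominance.
#' @param options A [reml_options()] list.
#' @return An object of class `reml_fit` with elements `sigma_a2`,
#'   `sigma_d2`, `sigma_p2`, `sigma_e2` (excluded components are `NA`),
#'   `loglik`, `converged`, `n_iterations`, `standard_errors`, `pinned`
#'   (components at the floor), `floor`, and the log-likelihood `trajectory`.
#' @export
reml_estimate <- function(design, G, D = NULL, options = reml_options()) {
  if (!inherits(design, "design_set")) abort("`design` must come from build_design().")
  pre <- reml_precompute(design, G, D)
  comp <- pre$components
  vy <- var(pre$y)
  floor_v <- options$floor_frac * vy

  # starting values: share of the fixed-effect-adjusted variance
  r0 <- stats::lm.fit(pre$X, pre$y)$residuals
  v0 <- var(r0)
  theta <- c(
    sigma_a2 = 0.3 * v0,
    sigma_p2 = if (pre$has_p) 0.1 * v0 else NULL,
    sigma_d2 = if (pre$has_d) 0.1 * v0 else NULL,
    sigma_e2 = 0.5 * v0
  )[comp]
  if (!is.null(options$init)) {
    ok <- intersect(names(options$init), comp)
    theta[ok] <- pmax(options$init[ok], floor_v)
  }

  ev <- reml_eval(theta, pre, derivs = TRUE)
  if (!is.finite(ev$ll)) {
    abort(paste(
      "Restricted likelihood is not computable at the starting values;",
      "the relationship matrices are likely singular - apply regularize() first."
    ))
  }
  trajectory <- ev$ll
  converged <- FALSE
  n_em <- 0L
  it <- 0L

  try_step <- function(delta, theta, ll_ref) {
    # step-halving acceptance: returns the accepted state or NULL
    for (h in 0:12) {
      cand <- pmax(theta + delta / 2^h, floor_v)
      if (all(cand == theta)) return(NULL)
      ev_c <- reml_eval(cand, pre, derivs = FALSE)
      if (is.finite(ev_c$ll) && ev_c$ll > ll_ref - 1e-12) {
        return(list(theta = cand, ll = ev_c$ll))
      }
    }
    NULL
  }

  for (it in seq_len(options$max_iter)) {
    pinned <- theta <= floor_v * (1 + 1e-12) & ev$score < 0
    free <- which(!pinned)
    if (!length(free)) break
    delta <- rep(0, length(comp))
    ai_free <- ev$AI[free, free, drop = FALSE]
    d_free <- tryCatch(
      solve(ai_free, ev$score[free]),
      error = function(e) NULL
    )
    step <- NULL
    if (!is.null(d_free) && all(is.finite(d_free))) {
      delta[free] <- d_free
      step <- try_step(delta, theta, ev$ll)
    }
    if (is.null(step)) {
      # EM-style fallback: guaranteed-direction update, still ll-checked
      n_em <- n_em + 1L
      rank_i <- ifelse(comp == "sigma_e2", pre$n, pre$q)
      # score = -0.5 (trPV - quad), so quad - trPV = 2 * score
      em_delta <- theta^2 / rank_i * (2 * ev$score)
      em_delta[pinned] <- 0
      step <- try_step(em_delta, theta, ev$ll)
    }
    if (is.null(step)) break # no improving step found
    ll_prev <- ev$ll
    theta <- step$theta
    ev <- reml_eval(theta, pre, derivs = TRUE)
    trajectory <- c(trajectory, ev$ll)
    if (options$verbose) {
      cat(sprintf("iter %3d  logLik %.6f\n", it, ev$ll))
    }
    if (abs(ev$ll - ll_prev) / (abs(ll_prev) + 1e-10) < options$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf(
      "REML did not meet the convergence tolerance in %d iterations.", it
    ))
  }

  se_free <- rep(NA_real_, length(comp))
  pinned <- theta <= floor_v * (1 + 1e-12)
  free <- which(!pinned)
  if (length(free)) {
    ai_inv <- tryCatch(solve(ev$AI[free, free, drop = FALSE]), error = function(e) NULL)
    if (!is.null(ai_inv)) se_free[free] <- sqrt(pmax(diag(ai_inv), 0))
  }

  get <- function(nm) if (nm %in% comp) unname(theta[nm]) else NA_real_
  structure(
    list(
      sigma_a2 = get("sigma_a2"),
      sigma_d2 = get("sigma_d2"),
      sigma_p2 = get("sigma_p2"),
      sigma_e2 = get("sigma_e2"),
      components = comp,
      loglik = ev$ll,
      converged = converged,
      n_iterations = it,
      n_em_steps = n_em,
      standard_errors = setNames(se_free, comp),
      pinned = comp[pinned],
      floor = floor_v,
      trajectory = trajectory
    ),
    class = "reml_fit"
  )
}

#' @exportS3Method base::print
print.reml_fit <- function(x, ...) {
  cat("<reml_fit>", if (x$converged) "converged" else "NOT converged",
      sprintf("in %d iterations, logLik %.4f\n", x$n_iterations, x$loglik))
  est <- c(
    sigma_a2 = x$sigma_a2, sigma_d2 = x$sigma_d2,
    sigma_p2 = x$sigma_p2, sigma_e2 = x$sigma_e2
  )
  for (nm in names(est)) {
    if (!is.na(est[nm])) {
      cat(sprintf(
        "  %-9s %12.6g%s\n", nm, est[nm],
        if (nm %in% x$pinned) " (at floor)" else ""
      ))
    }
  }
  invisible(x)
}

# Restricted log-likelihood at fixed variance components (used by tests and
# by grid-search cross-checks).
#' Restricted log-likelihood at given variance components
#'
#' Evaluates (up to an additive constant) the restricted log-likelihood of
#' the repeated-record animal model at fixed variance components, without
#' estimating anything. Useful for profiling and for cross-checks.
#'
#' @inheritParams reml_estimate
#' @param vc Named numeric vector or list with the included components among
#'   `sigma_a2`, `sigma_p2`, `sigma_d2`, `sigma_e2`.
#' @return The restricted log-likelihood (scalar; `-Inf` when the implied
#'   covariance is not positive definite).
#' @export
reml_loglik <- function(design, G, D = NULL, vc) {
  pre <- reml_precompute(design, G, D)
  theta <- setNames(
    vapply(pre$components, function(nm) as.numeric(vc[[nm]]), numeric(1)),
    pre$components
  )
  reml_eval(theta, pre, derivs = FALSE)$ll
}
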