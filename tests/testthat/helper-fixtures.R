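# Small in-code fixtures shared across test files.

# A complete toy panel with repeated records and a trait of known architecture.
make_toy_data <- function(n = 60, m = 300, n_qtl = 20, seed = 1,
                          sigma_a2 = 4, sigma_d2 = 1, sigma_p2 = 2, sigma_e2 = 3,
                          records = c(2L, 4L), qtl_indices = NULL) {
  cfg <- sim_config(
    n_individuals = n, n_snps = m, n_qtl = n_qtl,
    records_per_individual = records,
    fixed_effect_levels = c(flock = 3L, sex = 2L, age = 4L, year = 3L),
    seed = seed
  )
  geno <- simulate_genotypes(cfg)
  arch <- simulate_trait(
    geno, n_qtl, sigma_a2, sigma_d2, sigma_p2, sigma_e2,
    qtl_indices = qtl_indices, seed = seed + 1000L
  )
  pheno <- simulate_phenotypes(geno, arch, cfg, seed = seed + 2000L)
  list(cfg = cfg, geno = geno, arch = arch, pheno = pheno)
}

# Dense-matrix restricted log-likelihood, the independent oracle for REML.
brute_reml_loglik <- function(design, Gv, Dv = NULL, sa, sp = NULL, sd2 = NULL, se) {
  Z <- as.matrix(design$Z)
  X <- design$X
  y <- design$y
  K <- sa * Gv
  if (!is.null(sp)) K <- K + sp * diag(nrow(Gv))
  if (!is.null(sd2)) K <- K + sd2 * Dv
  V <- Z %*% K %*% t(Z) + se * diag(length(y))
  Vi <- solve(V)
  B <- t(X) %*% Vi %*% X
  b <- solve(B, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(B)$modulus +
                       t(r) %*% Vi %*% r))
}

# Direct conditional-expectation (GLS/BLUP) oracle for the mixed model with
# any combination of random terms sharing the incidence Z.
blup_oracle <- function(design, Gv, Dv = NULL, vc) {
  Z <- as.matrix(design$Z)
  X <- design$X
  y <- design$y
  K <- vc$sigma_a2 * Gv
  if (!is.null(vc$sigma_p2) && !is.na(vc$sigma_p2)) K <- K + vc$sigma_p2 * diag(nrow(Gv))
  if (!is.null(vc$sigma_d2) && !is.na(vc$sigma_d2)) K <- K + vc$sigma_d2 * Dv
  V <- Z %*% K %*% t(Z) + vc$sigma_e2 * diag(length(y))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  resid <- y - X %*% b
  u <- vc$sigma_a2 * Gv %*% t(Z) %*% Vi %*% resid
  p <- if (!is.null(vc$sigma_p2) && !is.na(vc$sigma_p2)) {
    vc$sigma_p2 * t(Z) %*% Vi %*% resid
  }
  d <- if (!is.null(vc$sigma_d2) && !is.na(vc$sigma_d2)) {
    vc$sigma_d2 * Dv %*% t(Z) %*% Vi %*% resid
  }
  list(b = as.numeric(b), u = as.numeric(u),
       p = if (!is.null(p)) as.numeric(p), d = if (!is.null(d)) as.numeric(d))
}
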