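test_that("design matrices tally records correctly", {
  ph <- tibble::tibble(
    individual_id = c("a", "a", "a", "b"),
    value = c(1, 2, 3, 4),
    flock = factor(c("f1", "f1", "f2", "f2")),
    sex = factor(c("m", "m", "m", "f")),
    age = factor("a1"), year = factor("y1")
  )
  des <- build_design(ph, model_spec(), individual_order = c("a", "b", "c"))
  # single-level factors drop out; intercept retained
  expect_true("(Intercept)" %in% colnames(des$X))
  expect_equal(des$counts, c(3, 1, 0))
  expect_equal(Matrix::colSums(des$Z)[["a"]], 3)
  # hand tallies of the cross-products
  ZtZ <- as.matrix(Matrix::crossprod(des$Z))
  expect_equal(unname(diag(ZtZ)), c(3, 1, 0))
  XtX <- crossprod(des$X)
  expect_equal(XtX["(Intercept)", "(Intercept)"], 4)
  expect_equal(XtX["flockf2", "flockf2"], 2)
})

test_that("MME solutions equal the conditional-expectation oracle on random toys", {
  for (seed in 1:6) {
    n_ind <- sample(5:10, 1)
    toy <- make_toy_data(
      n = n_ind, m = 50, n_qtl = 10, seed = seed,
      sigma_a2 = 2, sigma_d2 = 1, sigma_p2 = 1.5, sigma_e2 = 1,
      records = c(1L, 3L)
    )
    G <- regularize(build_additive_grm(toy$geno), 1e-4)
    D <- regularize(build_dominance_grm(toy$geno), 1e-4)
    vc <- list(sigma_a2 = 2.2, sigma_p2 = 1.4, sigma_d2 = 0.8, sigma_e2 = 1.1)
    des <- build_design(toy$pheno, model_spec(), toy$geno$individual_ids)
    sol <- solve_mme(des, G, D, vc)
    oracle <- blup_oracle(des, G$values, D$values, vc)
    expect_equal(unname(sol$b_hat), oracle$b, tolerance = 1e-8)
    expect_equal(unname(sol$u_hat), oracle$u, tolerance = 1e-8)
    expect_equal(unname(sol$p_hat), oracle$p, tolerance = 1e-8)
    expect_equal(unname(sol$d_hat), oracle$d, tolerance = 1e-8)
  }
})

test_that("additive-only MME matches the GLS/BLUP identity with single records", {
  toy <- make_toy_data(
    n = 5, m = 40, n_qtl = 8, seed = 11,
    sigma_a2 = 2, sigma_d2 = 0, sigma_p2 = 0, sigma_e2 = 1,
    records = c(1L, 1L)
  )
  spec <- model_spec(include_dominance = FALSE, include_permanent_env = FALSE)
  des <- build_design(toy$pheno, spec, toy$geno$individual_ids)
  G <- regularize(build_additive_grm(toy$geno), 1e-4)
  vc <- list(sigma_a2 = 1.5, sigma_e2 = 0.7)
  sol <- solve_mme(des, G, vc = vc)
  oracle <- blup_oracle(des, G$values, NULL,
                        list(sigma_a2 = 1.5, sigma_e2 = 0.7))
  expect_equal(unname(sol$u_hat), oracle$u, tolerance = 1e-8)
  expect_null(sol$p_hat)
  expect_null(sol$d_hat)
})

test_that("infinite shrinkage and replication invariance behave as expected", {
  toy <- make_toy_data(n = 10, m = 40, seed = 13, records = c(2L, 2L))
  spec <- model_spec(include_dominance = FALSE, include_permanent_env = FALSE)
  des <- build_design(toy$pheno, spec, toy$geno$individual_ids)
  G <- regularize(build_additive_grm(toy$geno), 1e-4)
  # sigma_a2 -> 0: u_hat -> 0
  sol0 <- solve_mme(des, G, vc = list(sigma_a2 = 1e-10, sigma_e2 = 1))
  expect_lt(max(abs(sol0$u_hat)), 1e-6)
  # duplicating every record is equivalent to halving the residual variance:
  # the duplicate pair's mean carries residual variance sigma_e2 / 2
  ph2 <- dplyr::bind_rows(toy$pheno, toy$pheno)
  des2 <- build_design(ph2, spec, toy$geno$individual_ids)
  dup <- solve_mme(des2, G, vc = list(sigma_a2 = 1.3, sigma_e2 = 0.9))
  half <- solve_mme(des, G, vc = list(sigma_a2 = 1.3, sigma_e2 = 0.45))
  expect_equal(dup$b_hat, half$b_hat, tolerance = 1e-8)
  expect_equal(dup$u_hat, half$u_hat, tolerance = 1e-8)
})

test_that("restricted likelihood matches the dense-matrix oracle", {
  toy <- make_toy_data(n = 12, m = 60, seed = 17)
  G <- regularize(build_additive_grm(toy$geno), 1e-4)
  D <- regularize(build_dominance_grm(toy$geno), 1e-4)
  des <- build_design(toy$pheno, model_spec(), toy$geno$individual_ids)
  ll_pkg <- reml_loglik(des, G, D, list(
    sigma_a2 = 3.1, sigma_p2 = 1.7, sigma_d2 = 0.9, sigma_e2 = 2.5
  ))
  ll_brute <- brute_reml_loglik(des, G$values, D$values,
                                sa = 3.1, sp = 1.7, sd2 = 0.9, se = 2.5)
  expect_equal(ll_pkg, ll_brute, tolerance = 1e-8)
})

test_that("REML optimum agrees with a brute-force grid search on a small toy", {
  toy <- make_toy_data(
    n = 30, m = 100, n_qtl = 20, seed = 19,
    sigma_a2 = 3, sigma_d2 = 0, sigma_p2 = 0, sigma_e2 = 2,
    records = c(2L, 3L)
  )
  spec <- model_spec(include_dominance = FALSE, include_permanent_env = FALSE)
  des <- build_design(toy$pheno, spec, toy$geno$individual_ids)
  G <- regularize(build_additive_grm(toy$geno), 1e-4)
  fit <- reml_estimate(des, G, options = reml_options())
  grid <- expand.grid(
    sa = seq(0.2, 8, by = 0.1),
    se = seq(0.2, 8, by = 0.1)
  )
  lls <- mapply(
    function(sa, se) reml_loglik(des, G, vc = list(sigma_a2 = sa, sigma_e2 = se)),
    grid$sa, grid$se
  )
  best <- grid[which.max(lls), ]
  expect_lt(abs(fit$sigma_a2 - best$sa), 0.1 + 1e-9)
  expect_lt(abs(fit$sigma_e2 - best$se), 0.1 + 1e-9)
  expect_gte(fit$loglik, max(lls) - 1e-6)
})

test_that("pure-noise data drive the genetic components to the floor", {
  toy <- make_toy_data(
    n = 80, m = 100, n_qtl = 10, seed = 23,
    sigma_a2 = 0, sigma_d2 = 0, sigma_p2 = 0, sigma_e2 = 5
  )
  des <- build_design(toy$pheno, model_spec(), toy$geno$individual_ids)
  G <- regularize(build_additive_grm(toy$geno), 1e-4)
  D <- regularize(build_dominance_grm(toy$geno), 1e-4)
  fit <- reml_estimate(des, G, D)
  expect_true(all(c("sigma_a2", "sigma_d2") %in% fit$pinned) ||
                (fit$sigma_a2 + fit$sigma_d2) < 0.05 * fit$sigma_e2)
  # the null restricted likelihood (residual-only) should be essentially equal
  ll_null <- reml_loglik(des, G, D, list(
    sigma_a2 = fit$floor, sigma_p2 = fit$floor,
    sigma_d2 = fit$floor, sigma_e2 = var(stats::lm.fit(des$X, des$y)$residuals)
  ))
  expect_lt(abs(fit$loglik - ll_null), 0.5)
})

test_that("log-likelihood trajectory is monotone non-decreasing", {
  toy <- make_toy_data(n = 50, m = 80, seed = 29)
  des <- build_design(toy$pheno, model_spec(), toy$geno$individual_ids)
  G <- regularize(build_additive_grm(toy$geno), 1e-4)
  D <- regularize(build_dominance_grm(toy$geno), 1e-4)
  fit <- reml_estimate(des, G, D)
  expect_true(all(diff(fit$trajectory) > -1e-9))
})

test_that("genetic parameters reproduce the reference worked examples", {
  # cashmere-yield-like components
  gp1 <- genetic_parameters(list(
    sigma_a2 = 9672.55, sigma_d2 = 2049.59, sigma_p2 = 4.40e-7, sigma_e2 = 26699.68
  ))
  expect_equal(round(gp1$h2_additive, 3), 0.252)
  expect_equal(round(gp1$h2_dominance, 3), 0.053)
  expect_equal(round(gp1$repeatability, 3), 0.305)
  # body-weight-like components
  gp2 <- genetic_parameters(list(
    sigma_a2 = 9.90, sigma_d2 = 6.31e-7, sigma_p2 = 2.85, sigma_e2 = 17.22
  ))
  expect_equal(round(gp2$h2_additive, 3), 0.330)
  expect_equal(round(gp2$repeatability, 3), 0.425)
  # simple quarter-heritability check
  gp3 <- genetic_parameters(list(sigma_a2 = 1, sigma_e2 = 3))
  expect_equal(gp3$h2_additive, 0.25)
  expect_equal(gp3$repeatability, 0.25)
})

test_that("genetic parameters are scale-invariant and bounded", {
  vc <- list(sigma_a2 = 2, sigma_d2 = 0.5, sigma_p2 = 1, sigma_e2 = 4)
  gp <- genetic_parameters(vc)
  gp_scaled <- genetic_parameters(lapply(vc, `*`, 1234.5))
  expect_equal(gp, gp_scaled, tolerance = 1e-12)
  expect_lte(gp$h2_additive + gp$h2_dominance, gp$repeatability + 1e-12)
  expect_lte(gp$repeatability, 1)
  expect_error(genetic_parameters(list(sigma_a2 = 0, sigma_e2 = 0)), "positive")
})

test_that("tidy and glance methods expose the fit in broom style", {
  toy <- make_toy_data(n = 40, m = 60, seed = 31)
  des <- build_design(toy$pheno, model_spec(), toy$geno$individual_ids)
  G <- regularize(build_additive_grm(toy$geno), 1e-4)
  D <- regularize(build_dominance_grm(toy$geno), 1e-4)
  fit <- reml_estimate(des, G, D)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$component, c("sigma_a2", "sigma_p2", "sigma_d2", "sigma_e2"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(is.logical(gl$converged))
})
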