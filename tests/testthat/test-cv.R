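test_that("fold assignment is a balanced partition, deterministic per seed", {
  ids <- sprintf("i%03d", 1:10)
  f <- assign_folds(ids, k = 5, seed = 1)
  expect_setequal(f$individual_id, ids)
  expect_equal(as.integer(table(f$fold)), rep(2L, 5))

  ids2 <- sprintf("i%03d", 1:23)
  f2 <- assign_folds(ids2, k = 5, seed = 1)
  sizes <- table(f2$fold)
  expect_lte(diff(range(sizes)), 1)
  expect_identical(assign_folds(ids2, k = 5, seed = 1), f2)
  expect_false(identical(assign_folds(ids2, k = 5, seed = 2)$fold, f2$fold))
  expect_error(assign_folds(ids[1:3], k = 5), "at least")
})

test_that("adjusted phenotypes subtract training fixed effects per record", {
  toy <- make_toy_data(n = 20, m = 50, seed = 51)
  spec <- model_spec()
  des <- build_design(toy$pheno, spec, toy$geno$individual_ids)
  G <- regularize(build_additive_grm(toy$geno), 1e-4)
  D <- regularize(build_dominance_grm(toy$geno), 1e-4)
  vc <- list(sigma_a2 = 1, sigma_p2 = 1, sigma_d2 = 1, sigma_e2 = 1)
  sol <- solve_mme(des, G, D, vc)
  adj <- adjusted_phenotypes(toy$pheno, sol)
  # hand recomputation for one individual
  id <- adj$individual_id[1]
  rows <- toy$pheno[toy$pheno$individual_id == id, ]
  dat <- rows
  for (f in names(sol$xlev)) dat[[f]] <- factor(as.character(dat[[f]]), sol$xlev[[f]])
  Xr <- model.matrix(sol$formula, dat)[, names(sol$b_hat), drop = FALSE]
  expect_equal(
    adj$adjusted[1],
    mean(rows$value - as.numeric(Xr %*% sol$b_hat)),
    tolerance = 1e-10
  )
  # records with unseen factor levels are dropped with a warning
  odd <- rows[1, ]
  odd$flock <- factor("not_a_flock")
  expect_warning(adjusted_phenotypes(dplyr::bind_rows(toy$pheno, odd), sol), "unseen")
})

test_that("accuracy conventions behave on known inputs", {
  set.seed(61)
  bv <- rnorm(200)
  # perfect prediction at h2 = 1
  expect_equal(prediction_accuracy(bv, bv, 1, "cor_over_h"), 1)
  # independent prediction: accuracy near zero
  expect_lt(abs(prediction_accuracy(bv, rnorm(200), 1)), 0.2)
  # known noise ratio: correlation has a closed form
  noise_var <- 0.5
  gebv <- bv + rnorm(200, 0, sqrt(noise_var))
  h2 <- 0.4
  expected <- sqrt(1 / (1 + noise_var)) / sqrt(h2)
  acc <- prediction_accuracy(bv, gebv, h2)
  expect_lt(abs(acc - expected), 0.15)
  # literal convention: cov / h2
  expect_equal(
    prediction_accuracy(bv, gebv, h2, "literal_cov_over_h2"),
    cov(bv, gebv) / h2
  )
  expect_warning(acc0 <- prediction_accuracy(bv, rep(1, 200), 0.3), "Zero variance")
  expect_true(is.na(acc0))
})

test_that("plain GBLUP cross-validation runs and reports coherent folds", {
  toy <- make_toy_data(
    n = 120, m = 400, n_qtl = 40, seed = 63,
    sigma_a2 = 10, sigma_d2 = 0, sigma_p2 = 1, sigma_e2 = 8
  )
  spec <- model_spec(include_dominance = FALSE)
  rep_none <- run_cv(toy$geno, toy$pheno, "none", spec = spec, seed = 5,
                     options = reml_options(tol = 1e-7))
  expect_s3_class(rep_none, "cv_report")
  expect_equal(nrow(rep_none), 5)
  expect_equal(sum(rep_none$n_validation), 120)
  expect_true(all(is.na(rep_none$tau)))
  gl <- glance(rep_none)
  expect_equal(gl$mean_accuracy, mean(rep_none$accuracy))
  # a heritable trait should be predicted far better than chance
  expect_gt(gl$mean_accuracy, 0.3)
})

test_that("prior-informed cross-validation uses training-only information", {
  toy <- make_toy_data(
    n = 100, m = 300, n_qtl = 30, seed = 67,
    sigma_a2 = 10, sigma_d2 = 2, sigma_p2 = 0.5, sigma_e2 = 6,
    qtl_indices = 1:30
  )
  pv <- tibble::tibble(
    snp_id = toy$geno$snp_ids, chrom = toy$geno$map$chrom, pos = toy$geno$map$pos,
    p_value = c(seq(1e-6, 1e-4, length.out = 30), runif(270, 0.2, 1))
  )
  opts <- reml_options(tol = 1e-6, max_iter = 60)
  expect_message(
    rep_top <- run_cv(toy$geno, toy$pheno, "top10", pvals = pv, seed = 5, options = opts),
    "leakage-free"
  )
  expect_true(all(rep_top$tau > 0.5))

  # hygiene: perturbing validation phenotypes leaves the training chain alone
  folds <- assign_folds(toy$geno$individual_ids, 5, seed = 5)
  val1 <- folds$individual_id[folds$fold == 1]
  ph2 <- toy$pheno
  ph2$value[ph2$individual_id %in% val1] <- ph2$value[ph2$individual_id %in% val1] + 1000
  suppressMessages({
    r1 <- run_cv(toy$geno, toy$pheno, "top10", pvals = pv, folds = folds, options = opts)
    r2 <- run_cv(toy$geno, ph2, "top10", pvals = pv, folds = folds, options = opts)
  })
  expect_identical(r1$tau[1], r2$tau[1])
  expect_identical(r1$h2[1], r2$h2[1])
})

test_that("scenario comparison reproduces the one-way ANOVA identity", {
  rep_a <- tibble::tibble(scenario = "none", accuracy = c(0.5, 0.6, 0.55, 0.52, 0.58))
  rep_b <- tibble::tibble(scenario = "top5", accuracy = c(0.7, 0.72, 0.69, 0.71, 0.68))
  cmp <- compare_scenarios(list(rep_a, rep_b))
  # hand sums of squares for the 2 x 5 layout
  all_acc <- c(rep_a$accuracy, rep_b$accuracy)
  grand <- mean(all_acc)
  ss_between <- 5 * ((mean(rep_a$accuracy) - grand)^2 + (mean(rep_b$accuracy) - grand)^2)
  ss_within <- sum((rep_a$accuracy - mean(rep_a$accuracy))^2) +
    sum((rep_b$accuracy - mean(rep_b$accuracy))^2)
  f_hand <- (ss_between / 1) / (ss_within / 8)
  expect_equal(cmp$anova$statistic[1], f_hand, tolerance = 1e-10)
  expect_lt(cmp$anova$p.value[1], 0.001)

  # identical accuracies: F ~ 0, p ~ 1
  same <- tibble::tibble(
    scenario = rep(c("none", "top5"), each = 4),
    accuracy = rep(0.6, 8) + rep(c(-0.01, 0.01), 4)
  )
  cmp0 <- compare_scenarios(same)
  expect_lt(cmp0$anova$statistic[1], 1e-10)
  expect_gt(cmp0$anova$p.value[1], 0.99)
  expect_error(compare_scenarios(rep_a), "two scenarios")
})
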