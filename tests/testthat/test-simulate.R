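test_that("genotype simulation follows Hardy-Weinberg and is deterministic", {
  cfg <- sim_config(n_individuals = 2000, n_snps = 50, maf_range = c(0.5, 0.5), seed = 7)
  geno <- simulate_genotypes(cfg)
  # at p = 0.5 the observed frequency and heterozygosity are both near 0.5
  expect_lt(max(abs(geno$allele_freq - 0.5)), 0.05)
  het <- colMeans(geno$codes == 1)
  expect_lt(max(abs(het - 0.5)), 0.06)
  expect_false(anyNA(geno$codes))

  again <- simulate_genotypes(cfg)
  expect_identical(geno$codes, again$codes)
  other <- simulate_genotypes(cfg, seed = 8)
  expect_false(identical(geno$codes, other$codes))
})

test_that("simulated panels give VanRaden matrices with unit mean diagonal", {
  cfg <- sim_config(n_individuals = 2000, n_snps = 5000, maf_range = c(0.05, 0.5), seed = 3)
  geno <- simulate_genotypes(cfg)
  G <- build_additive_grm(geno)
  expect_lt(abs(mean(diag(G$values)) - 1), 0.05)
})

test_that("LD block simulation correlates SNPs within blocks only", {
  cfg <- sim_config(
    n_individuals = 800, n_snps = 40, maf_range = c(0.2, 0.4),
    ld_block_size = 5L, ld_within_r = 0.95, seed = 11
  )
  geno <- simulate_genotypes(cfg)
  cors <- cor(geno$codes)
  within <- cors[1, 2:5]
  between <- cors[1, 6:10]
  expect_gt(min(abs(within)), 0.5)
  expect_lt(max(abs(between)), 0.2)
})

test_that("trait architecture realises target variances exactly", {
  toy <- make_toy_data(n = 200, m = 400, seed = 5,
                       sigma_a2 = 9672.55, sigma_d2 = 2049.59,
                       sigma_p2 = 0, sigma_e2 = 26699.68)
  # exact rescaling: realised variances equal targets to float precision
  expect_equal(var(toy$arch$true_breeding_values), 9672.55, tolerance = 1e-12)
  expect_equal(var(toy$arch$true_dominance_values), 2049.59, tolerance = 1e-12)

  # brute-force recomputation of the breeding values from codes and effects
  scores <- as.numeric(toy$geno$codes[, toy$arch$qtl_indices] %*% toy$arch$additive_effects)
  expect_equal(unname(toy$arch$true_breeding_values), scores - mean(scores),
               tolerance = 1e-10)

  # zero additive target: all effects and breeding values vanish
  null_arch <- simulate_trait(toy$geno, 20, sigma_a2 = 0, sigma_d2 = 0,
                              sigma_e2 = 1, seed = 3)
  expect_true(all(null_arch$additive_effects == 0))
  expect_true(all(null_arch$true_breeding_values == 0))
})

test_that("phenotype records decompose into their generative parts", {
  # no variance anywhere: every record equals the mean
  cfg <- sim_config(n_individuals = 30, n_snps = 50, seed = 2)
  geno <- simulate_genotypes(cfg)
  arch0 <- simulate_trait(geno, 10, 0, 0, sigma_p2 = 0, sigma_e2 = 0, seed = 4)
  ph0 <- simulate_phenotypes(geno, arch0, cfg, mu = 772.05)
  expect_true(all(ph0$value == 772.05))

  # permanent environment only: records identical within, different between
  archp <- simulate_trait(geno, 10, 0, 0, sigma_p2 = 50, sigma_e2 = 0, seed = 4)
  php <- simulate_phenotypes(geno, archp, cfg, mu = 0)
  per_ind_sd <- tapply(php$value, php$individual_id, sd)
  expect_true(all(per_ind_sd == 0))
  expect_gt(sd(tapply(php$value, php$individual_id, mean)), 0)
})

test_that("phenotypic variance matches the component sum under the CY regime", {
  toy <- make_toy_data(n = 2000, m = 1000, n_qtl = 100, seed = 9,
                       sigma_a2 = 9672.55, sigma_d2 = 2049.59,
                       sigma_p2 = 0, sigma_e2 = 26699.68)
  # fixed effects add spread, so compare within-cell-adjusted records
  fit <- lm(value ~ flock + sex + age + year, data = toy$pheno)
  total <- 9672.55 + 2049.59 + 0 + 26699.68
  expect_lt(abs(var(residuals(fit)) - total) / total, 0.10)
})

test_that("records-on-breeding-value regression has unit slope without dominance", {
  toy <- make_toy_data(n = 1000, m = 600, n_qtl = 60, seed = 13,
                       sigma_a2 = 10, sigma_d2 = 0, sigma_p2 = 0, sigma_e2 = 5)
  truth <- attr(toy$pheno, "truth")
  tbv <- truth$true_breeding_value[match(toy$pheno$individual_id, truth$individual_id)]
  slope <- coef(lm(toy$pheno$value ~ tbv + toy$pheno$flock + toy$pheno$sex +
                     toy$pheno$age + toy$pheno$year))[["tbv"]]
  expect_lt(abs(slope - 1), 0.05)
})

test_that("intraclass correlation of records converges to the repeatability", {
  sa <- 6; sd2 <- 2; sp <- 3; se <- 9
  toy <- make_toy_data(n = 1500, m = 500, n_qtl = 50, seed = 17,
                       sigma_a2 = sa, sigma_d2 = sd2, sigma_p2 = sp, sigma_e2 = se,
                       records = c(3L, 3L))
  truth <- attr(toy$pheno, "truth")
  ind_part <- truth$true_breeding_value + truth$true_dominance_value +
    truth$permanent_environment
  # between-individual variance of the individual-constant part over total
  icc_expected <- (sa + sd2 + sp) / (sa + sd2 + sp + se)
  adj <- residuals(lm(value ~ flock + sex + age + year, data = toy$pheno))
  ind <- factor(toy$pheno$individual_id)
  m1 <- tapply(adj, ind, mean)
  aov_between <- var(m1)
  within <- tapply(adj, ind, var)
  icc_obs <- (aov_between - mean(within) / 3) / (aov_between - mean(within) / 3 + mean(within))
  expect_lt(abs(icc_obs - icc_expected), 0.05)
})
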