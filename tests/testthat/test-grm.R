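two_by_two_panel <- function() {
  codes <- matrix(c(0, 2, 1, 1), nrow = 2) # individuals x SNPs: [[0,1],[2,1]]
  dimnames(codes) <- list(c("i1", "i2"), c("s1", "s2"))
  genotype_matrix(codes)
}

test_that("additive matrix matches the closed formula on a hand toy", {
  g <- two_by_two_panel()
  expect_equal(unname(g$allele_freq), c(0.5, 0.5))
  G <- build_additive_grm(g)
  # Z = [[-1, 0], [1, 0]], denominator 2 * (0.25 + 0.25) = 1
  expect_equal(G$scaling_denominator, 1.0)
  expect_equal(unname(G$values), matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12)
})

test_that("dominance matrix matches the closed formula on a hand toy", {
  g <- two_by_two_panel()
  D <- build_dominance_grm(g)
  # h = [[0,1],[0,1]], centered by 2pq = 0.5; denominator 4*(1/16+1/16) = 0.5
  expect_equal(D$scaling_denominator, 0.5)
  expect_equal(unname(D$values), matrix(1, 2, 2), tolerance = 1e-12)
})

test_that("additive matrix is centered: its grand sum is zero", {
  toy <- make_toy_data(n = 40, m = 120, seed = 31)
  G <- build_additive_grm(toy$geno)
  expect_lt(abs(sum(G$values)), 1e-7 * nrow(G$values)^2)
})

test_that("dominance diagonal matches its Hardy-Weinberg expectation", {
  cfg <- sim_config(n_individuals = 2000, n_snps = 2000, maf_range = c(0.05, 0.5), seed = 6)
  geno <- simulate_genotypes(cfg)
  D <- build_dominance_grm(geno)
  # under HWE, E[(h - 2pq)^2] = 2pq(1 - 2pq); the hybrid scaling uses 4 sum p^2 q^2
  p <- geno$allele_freq
  q <- 1 - p
  expected <- sum(2 * p * q * (1 - 2 * p * q)) / (4 * sum(p^2 * q^2))
  expect_lt(abs(mean(diag(D$values)) - expected) / expected, 0.05)
})

test_that("panels without heterozygotes give finite, PSD dominance matrices", {
  codes <- matrix(c(0, 2, 2, 0, 0, 2), nrow = 3)
  dimnames(codes) <- list(paste0("i", 1:3), c("s1", "s2"))
  g <- genotype_matrix(codes)
  D <- build_dominance_grm(g)
  expect_true(all(is.finite(D$values)))
  expect_gt(min(eigen(D$values, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("subset cross-products add up over a disjoint cover", {
  toy <- make_toy_data(n = 25, m = 60, seed = 33)
  geno <- toy$geno
  prior <- geno$snp_ids[1:20]
  resid <- geno$snp_ids[21:60]
  unscale <- function(R) R$values * R$scaling_denominator
  G_all <- build_additive_grm(geno)
  G1 <- build_additive_grm(geno, prior)
  G2 <- build_additive_grm(geno, resid)
  expect_equal(unscale(G_all), unscale(G1) + unscale(G2), tolerance = 1e-10)
  D_all <- build_dominance_grm(geno)
  D1 <- build_dominance_grm(geno, prior)
  D2 <- build_dominance_grm(geno, resid)
  expect_equal(unscale(D_all), unscale(D1) + unscale(D2), tolerance = 1e-10)
})

test_that("built matrices are PSD before any ridge", {
  for (seed in 1:3) {
    toy <- make_toy_data(n = 30, m = 20, seed = seed) # fewer SNPs than individuals
    for (R in list(build_additive_grm(toy$geno), build_dominance_grm(toy$geno))) {
      ev <- eigen(R$values, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-8)
    }
  }
})

test_that("convex combination obeys the formula, its bounds and fixed points", {
  toy <- make_toy_data(n = 12, m = 40, seed = 35)
  A <- build_additive_grm(toy$geno, toy$geno$snp_ids[1:15])
  B <- build_additive_grm(toy$geno, toy$geno$snp_ids[16:40])
  expect_equal(combine_matrices(A, B, 1)$values, A$values)
  expect_equal(combine_matrices(A, A, 0.5)$values, A$values)
  M <- combine_matrices(A, B, 0.64)
  expect_equal(M$values, 0.64 * A$values + 0.36 * B$values, tolerance = 1e-14)
  expect_true(all(M$values >= pmin(A$values, B$values) - 1e-12))
  expect_true(all(M$values <= pmax(A$values, B$values) + 1e-12))

  # 2x2 worked example
  ids <- c("a", "b")
  A2 <- relationship_matrix(matrix(c(1, 0, 0, 1), 2, dimnames = list(ids, ids)), "additive")
  B2 <- relationship_matrix(matrix(c(0, 1, 1, 0), 2, dimnames = list(ids, ids)), "additive")
  expect_equal(
    unname(combine_matrices(A2, B2, 0.64)$values),
    matrix(c(0.64, 0.36, 0.36, 0.64), 2)
  )
})

test_that("ridge regularisation shifts every eigenvalue by exactly the amount added", {
  toy <- make_toy_data(n = 20, m = 10, n_qtl = 5, seed = 37)
  G <- build_additive_grm(toy$geno)
  expect_identical(regularize(G, 0), G)
  Gr <- regularize(G, 1e-4)
  shift <- 1e-4 * mean(diag(G$values))
  ev0 <- eigen(G$values, symmetric = TRUE, only.values = TRUE)$values
  ev1 <- eigen(Gr$values, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev1, ev0 + shift, tolerance = 1e-10)
  expect_equal(Gr$ridge_added, shift)

  # a singular matrix becomes positive definite
  ids <- c("a", "b")
  S <- relationship_matrix(matrix(1, 2, 2, dimnames = list(ids, ids)), "additive")
  Sr <- regularize(S, 1e-6)
  expect_gt(min(eigen(Sr$values, only.values = TRUE)$values), 0)
})

test_that("misaligned or invalid inputs error clearly", {
  toy <- make_toy_data(n = 10, m = 20, seed = 39)
  A <- build_additive_grm(toy$geno)
  other <- make_toy_data(n = 10, m = 20, seed = 40)
  B <- build_additive_grm(other$geno)
  B$individual_ids <- rev(B$individual_ids)
  rownames(B$values) <- colnames(B$values) <- B$individual_ids
  expect_error(combine_matrices(A, B, 0.5), "not aligned")
  mono <- genotype_matrix(matrix(2, 4, 3, dimnames = list(paste0("i", 1:4), paste0("s", 1:3))))
  expect_error(build_additive_grm(mono), "monomorphic")
})
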