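#' Simulation configuration
#'
#' Bundles the dimensions and structure of a synthetic genotype/phenotype data
#' set emulating a cashmere-goat breeding population: a few thousand
#' genotyped individuals, a medium-density SNP panel, repeated trait records
#' per individual and four record-level fixed-effect factors (flock, sex, age,
#' year). Defaults are scaled down from the motivating population (~2,300
#' individuals at ~50,000 SNPs with ~4 records each) so that a full analysis
#' runs on a desktop.
#'
#' @param n_individuals Number of genotyped individuals.
#' @param n_snps Number of SNPs on the panel.
#' @param maf_range Interval in (0, 0.5] from which per-SNP allele frequencies
#'   are drawn uniformly.
#' @param n_qtl Number of causal loci used by [simulate_trait()] defaults.
#' @param records_per_individual Inclusive integer range for the number of
#'   repeated records per individual (default 2 to 5, averaging ~3.5).
#' @param fixed_effect_levels Named integer vector of level counts for the
#'   fixed-effect factors.
#' @param ld_block_size SNPs per linkage block; 1 (default) simulates
#'   independent SNPs, larger values copy alleles within a block.
#' @param ld_within_r Probability that a SNP in a block copies the block
#'   template allele on each gamete (ignored when `ld_block_size == 1`).
#' @param seed Integer seed driving all randomness derived from this config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 500, n_snps = 5000,
                       maf_range = c(0.05, 0.5), n_qtl = 100,
                       records_per_individual = c(2L, 5L),
                       fixed_effect_levels = c(flock = 5L, sex = 2L, age = 6L, year = 4L),
                       ld_block_size = 1L, ld_within_r = 0.9,
                       seed = 1L) {
  stopifnot_scalar_number(n_individuals, "n_individuals", 1)
  stopifnot_scalar_number(n_snps, "n_snps", 1)
  stopifnot_scalar_number(n_qtl, "n_qtl", 0)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an interval within (0, 0.5].")
  }
  if (length(records_per_individual) != 2 ||
      records_per_individual[1] < 1 ||
      records_per_individual[1] > records_per_individual[2]) {
    abort("`records_per_individual` must be an increasing pair of counts >= 1.")
  }
  if (is.null(names(fixed_effect_levels)) || any(fixed_effect_levels < 1)) {
    abort("`fixed_effect_levels` must be a named vector of positive counts.")
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      n_snps = as.integer(n_snps),
      maf_range = as.numeric(maf_range),
      n_qtl = as.integer(n_qtl),
      records_per_individual = as.integer(records_per_individual),
      fixed_effect_levels = fixed_effect_levels,
      ld_block_size = as.integer(ld_block_size),
      ld_within_r = ld_within_r,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Variance-component regimes of the four goat economic traits
#'
#' Whole-panel variance-component regimes for cashmere yield (CY, grams),
#' cashmere diameter (CD, micrometres), body weight (BW, kilograms) and
#' cashmere length (CL, centimetres), as estimated for the Inner Mongolia
#' cashmere goat population that motivates this package, together with the
#' population trait means. Cashmere length is conventionally modelled without
#' a dominance term (`sigma_d2 = NA`).
#'
#' @return A tibble with columns `trait`, `mean`, `sigma_a2`, `sigma_d2`,
#'   `sigma_p2`, `sigma_e2`.
#' @export
goat_trait_presets <- function() {
  tibble(
    trait = c("CY", "CD", "BW", "CL"),
    mean = c(772.05, 14.95, 37.20, 6.17),
    sigma_a2 = c(9672.55, 0.161, 8.96, 0.112),
    sigma_d2 = c(2049.59, 3.87e-7, 1.99e-6, NA_real_),
    sigma_p2 = c(4.40e-7, 4.71e-8, 3.22, 3.79e-6),
    sigma_e2 = c(26699.68, 0.381, 17.23, 0.928)
  )
}

#' Simulate a genotype panel
#'
#' Draws per-SNP allele frequencies uniformly from `config$maf_range` and
#' genotypes under Hardy-Weinberg proportions, with no missingness. With
#' `ld_block_size > 1`, SNPs within a block copy a template gamete with
#' probability `ld_within_r`, producing positive within-block linkage
#' disequilibrium.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(config, seed = NULL) {
  if (!inherits(config, "sim_config")) abort("`config` must be a `sim_config`.")
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  n <- config$n_individuals
  m <- config$n_snps
  with_seed(seed, {
    p <- runif(m, config$maf_range[1], config$maf_range[2])
    if (config$ld_block_size <= 1L) {
      codes <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
    } else {
      codes <- matrix(0L, n, m)
      blocks <- split(seq_len(m), (seq_len(m) - 1L) %/% config$ld_block_size)
      r <- config$ld_within_r
      for (blk in blocks) {
        # template gametes for the block, one pair per individual
        t1 <- rbinom(n, 1L, p[blk[1]])
        t2 <- rbinom(n, 1L, p[blk[1]])
        for (j in blk) {
          copy1 <- rbinom(n, 1L, r) == 1L
          copy2 <- rbinom(n, 1L, r) == 1L
          a1 <- ifelse(copy1, t1, rbinom(n, 1L, p[j]))
          a2 <- ifelse(copy2, t2, rbinom(n, 1L, p[j]))
          codes[, j] <- a1 + a2
        }
      }
    }
    storage.mode(codes) <- "double"
    rownames(codes) <- sprintf("ind_%04d", seq_len(n))
    colnames(codes) <- sprintf("snp_%05d", seq_len(m))
    # spread SNPs over 25 pseudo-chromosomes
    chrom <- ((seq_len(m) - 1L) %/% ceiling(m / 25)) + 1L
    pos <- stats::ave(seq_len(m), chrom, FUN = seq_along) * 1000L
    genotype_matrix(codes, tibble(snp_id = colnames(codes), chrom = chrom, pos = pos))
  })
}

#' Simulate a trait architecture on a genotype panel
#'
#' Samples `n_qtl` causal SNPs, draws additive and dominance effects from
#' zero-mean normals, and rescales each effect class so that the realised
#' variance (sample variance across individuals, denominator n - 1) of the
#' additive genotypic score equals `sigma_a2` exactly, and likewise the
#' dominance score and `sigma_d2`. Breeding values are the centered additive
#' scores; dominance values the centered heterozygosity scores.
#'
#' @param geno A [genotype_matrix()] with complete codes.
#' @param n_qtl Number of causal SNPs.
#' @param sigma_a2,sigma_d2 Target additive and dominance genotypic variances
#'   (squared trait units).
#' @param sigma_p2,sigma_e2 Target permanent-environment and residual
#'   variances, carried to [simulate_phenotypes()].
#' @param qtl_indices Optional SNP indices to use as causal loci (overrides
#'   random sampling; used e.g. to plant QTLs inside a prior marker set).
#' @param seed Integer seed.
#' @return A `trait_architecture` list with the QTL indices, per-QTL effects,
#'   target variances, and named `true_breeding_values` /
#'   `true_dominance_values` per individual.
#' @export
simulate_trait <- function(geno, n_qtl, sigma_a2, sigma_d2 = 0,
                           sigma_p2 = 0, sigma_e2 = 1,
                           qtl_indices = NULL, seed = 1L) {
  check_genotype_matrix(geno)
  for (v in c(sigma_a2, sigma_d2, sigma_p2, sigma_e2)) {
    stopifnot_scalar_number(v, "target variance", 0)
  }
  m <- ncol(geno$codes)
  if (is.null(qtl_indices)) {
    if (n_qtl > m) abort("`n_qtl` exceeds the number of SNPs.")
  } else {
    qtl_indices <- as.integer(qtl_indices)
    if (anyDuplicated(qtl_indices) || any(qtl_indices < 1 | qtl_indices > m)) {
      abort("`qtl_indices` must be unique indices within the SNP panel.")
    }
    n_qtl <- length(qtl_indices)
  }
  with_seed(seed, {
    if (is.null(qtl_indices)) qtl_indices <- sort(sample.int(m, n_qtl))
    q_codes <- geno$codes[, qtl_indices, drop = FALSE]
    if (anyNA(q_codes)) abort("Causal SNPs must have complete codes (run QC first).")
    n <- nrow(q_codes)

    rescale <- function(score, target, what) {
      v <- var(score)
      if (target == 0) {
        return(list(scale = 0, score = rep(0, n)))
      }
      if (v == 0) {
        abort(sprintf(
          "Cannot realise a positive %s variance: all causal SNPs are monomorphic for it.",
          what
        ))
      }
      s <- sqrt(target / v)
      list(scale = s, score = (score - mean(score)) * s)
    }

    a_eff <- rnorm(n_qtl)
    add_score <- as.numeric(q_codes %*% a_eff)
    add <- rescale(add_score, sigma_a2, "additive")
    a_eff <- a_eff * add$scale

    d_eff <- rnorm(n_qtl)
    het <- (q_codes == 1) * 1
    dom_score <- as.numeric(het %*% d_eff)
    dom <- rescale(dom_score, sigma_d2, "dominance")
    d_eff <- d_eff * dom$scale

    tbv <- setNames(add$score, geno$individual_ids)
    tdv <- setNames(dom$score, geno$individual_ids)
    structure(
      list(
        qtl_indices = qtl_indices,
        qtl_ids = geno$snp_ids[qtl_indices],
        additive_effects = a_eff,
        dominance_effects = d_eff,
        target_sigma_a2 = sigma_a2,
        target_sigma_d2 = sigma_d2,
        target_sigma_p2 = sigma_p2,
        target_sigma_e2 = sigma_e2,
        true_breeding_values = tbv,
        true_dominance_values = tdv
      ),
      class = "trait_architecture"
    )
  })
}

#' Simulate repeated phenotype records
#'
#' Generates 2-5 (configurable) records per individual under the
#' repeated-record animal model: record value = `mu` + fixed-effect level
#' values + true breeding value + true dominance value + an
#' individual-constant permanent-environment draw `N(0, sigma_p2)` + a
#' record-level residual `N(0, sigma_e2)`. Flock and sex are assigned per
#' individual; age and year vary across an individual's records (consecutive
#' measurement years). Fixed-effect level values are equally spaced offsets
#' spanning `effect_spread` residual standard deviations (default 1).
#'
#' @param geno A [genotype_matrix()].
#' @param arch A `trait_architecture` from [simulate_trait()] built on `geno`.
#' @param config A [sim_config()] (record counts and factor level counts).
#' @param mu Overall trait mean (default 0).
#' @param trait Trait label written into the table.
#' @param effect_spread Width of the fixed-effect offsets, in residual SDs.
#' @param seed Optional seed overriding `config$seed`.
#' @return A tibble with columns `individual_id`, `trait`, `value`, `flock`,
#'   `sex`, `age`, `year`, plus a `truth` attribute: a per-individual tibble
#'   of the true breeding value, dominance value and permanent-environment
#'   effect.
#' @export
simulate_phenotypes <- function(geno, arch, config, mu = 0, trait = "trait",
                                effect_spread = 1, seed = NULL) {
  check_genotype_matrix(geno)
  if (!inherits(arch, "trait_architecture")) {
    abort("`arch` must come from simulate_trait().")
  }
  if (!identical(names(arch$true_breeding_values), geno$individual_ids)) {
    abort("`arch` was not built on this genotype panel (individual ids differ).")
  }
  seed <- if (is.null(seed)) derive_seed(config$seed, 7L) else as.integer(seed)
  lv <- config$fixed_effect_levels
  sigma_e <- sqrt(arch$target_sigma_e2)
  with_seed(seed, {
    n <- length(geno$individual_ids)
    rec_rng <- config$records_per_individual
    rec_vals <- seq.int(rec_rng[1], rec_rng[2])
    n_rec <- rec_vals[sample.int(length(rec_vals), n, replace = TRUE)]

    # equally spaced level values spanning `effect_spread` residual SDs
    level_values <- lapply(lv, function(L) {
      if (L == 1L) 0 else seq(-0.5, 0.5, length.out = L) * effect_spread * sigma_e
    })

    flock_i <- sample.int(lv[["flock"]], n, replace = TRUE)
    sex_i <- sample.int(lv[["sex"]], n, replace = TRUE)
    pe_i <- rnorm(n, 0, sqrt(arch$target_sigma_p2))

    idx <- rep(seq_len(n), n_rec)
    rec_no <- sequence(n_rec)
    start_year <- sample.int(max(1L, lv[["year"]] - max(n_rec) + 1L), n, replace = TRUE)
    year <- pmin(start_year[idx] + rec_no - 1L, lv[["year"]])
    start_age <- sample.int(max(1L, lv[["age"]] - max(n_rec) + 1L), n, replace = TRUE)
    age <- pmin(start_age[idx] + rec_no - 1L, lv[["age"]])

    value <- mu +
      level_values[["flock"]][flock_i[idx]] +
      level_values[["sex"]][sex_i[idx]] +
      level_values[["age"]][age] +
      level_values[["year"]][year] +
      arch$true_breeding_values[idx] +
      arch$true_dominance_values[idx] +
      pe_i[idx] +
      rnorm(length(idx), 0, sigma_e)

    pheno <- tibble(
      individual_id = geno$individual_ids[idx],
      trait = trait,
      value = as.numeric(value),
      flock = factor(paste0("f", flock_i[idx])),
      sex = factor(paste0("s", sex_i[idx])),
      age = factor(paste0("a", age)),
      year = factor(paste0("y", year))
    )
    attr(pheno, "truth") <- tibble(
      individual_id = geno$individual_ids,
      true_breeding_value = unname(arch$true_breeding_values),
      true_dominance_value = unname(arch$true_dominance_values),
      permanent_environment = pe_i
    )
    pheno
  })
}
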