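#' Configuration for a full pipeline run
#'
#' Exactly one of `genotype_path` (with `phenotype_path`) or `simulation`
#' must be given: either the pipeline reads data from disk or it simulates
#' them. All randomness downstream is derived from `seed`.
#'
#' @param simulation A [sim_config()], or `NULL` when reading from disk.
#' @param genotype_path,genotype_format,phenotype_path,pvalue_path Input
#'   files: genotypes (see [read_genotypes()]), a record-level phenotype CSV
#'   with columns `individual_id`, `trait`, `value` and the fixed-effect
#'   factors, and optionally a per-SNP p-value TSV. When `pvalue_path` is
#'   `NULL` the built-in association scan supplies p-values.
#' @param trait_target For simulation: a row of [goat_trait_presets()] by
#'   trait name (default `"CY"`), fixing the generative variance components.
#' @param spec A [model_spec()].
#' @param scenarios Character vector of prior-information scenarios.
#' @param qc List of [qc_filter()] thresholds.
#' @param reml [reml_options()].
#' @param cv_k Folds for cross-validation.
#' @param ridge_factor Ridge for matrices destined for inversion.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            genotype_path = NULL, genotype_format = "csv",
                            phenotype_path = NULL, pvalue_path = NULL,
                            trait_target = "CY",
                            spec = model_spec(),
                            scenarios = c("none", "top5", "top10", "top15", "top20"),
                            qc = list(maf_min = 0.01, snp_callrate_min = 0.90,
                                      ind_callrate_min = 0.90),
                            reml = reml_options(),
                            cv_k = 5L, ridge_factor = 1e-6, seed = 1L) {
  if (is.null(simulation) == is.null(genotype_path)) {
    abort("Give exactly one of `simulation` or `genotype_path`.")
  }
  if (!is.null(genotype_path) && is.null(phenotype_path)) {
    abort("`phenotype_path` is required when reading genotypes from disk.")
  }
  structure(
    list(
      simulation = simulation,
      genotype_path = genotype_path, genotype_format = genotype_format,
      phenotype_path = phenotype_path, pvalue_path = pvalue_path,
      trait_target = trait_target, spec = spec, scenarios = scenarios,
      qc = qc, reml = reml, cv_k = as.integer(cv_k),
      ridge_factor = ridge_factor, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full GBLUP-GA analysis pipeline
#'
#' Executes simulate/read, quality control, the association scan (unless
#' p-values are supplied), and for every scenario the partition, the
#' partition fits, the weight tau, the weighted matrices, the refit and the
#' cross-validation; writes tidy CSV artifacts, a scenario comparison and a
#' JSON manifest to `out_dir`. Reruns with the same config are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the variance-component table, per-scenario
#'   `cv_report`s, the scenario comparison and the manifest.
#' @export
run_pipeline <- function(config, out_dir = tempfile("gablup_run_")) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }

  # --- data -----------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulation)) {
    log_line("simulating genotypes (%d x %d)", config$simulation$n_individuals,
             config$simulation$n_snps)
    geno <- simulate_genotypes(config$simulation, seed = config$seed)
    preset <- goat_trait_presets()
    row <- preset[preset$trait == config$trait_target, ]
    if (nrow(row) != 1) abort(sprintf("Unknown trait target '%s'.", config$trait_target))
    include_d <- config$spec$include_dominance && !is.na(row$sigma_d2)
    arch <- simulate_trait(
      geno,
      n_qtl = config$simulation$n_qtl,
      sigma_a2 = row$sigma_a2,
      sigma_d2 = if (include_d) row$sigma_d2 else 0,
      sigma_p2 = row$sigma_p2,
      sigma_e2 = row$sigma_e2,
      seed = derive_seed(config$seed, 11L)
    )
    pheno <- simulate_phenotypes(
      geno, arch, config$simulation,
      mu = row$mean, trait = row$trait,
      seed = derive_seed(config$seed, 23L)
    )
    truth <- attr(pheno, "truth")
  } else {
    log_line("reading genotypes from %s", config$genotype_path)
    geno <- read_genotypes(config$genotype_path, config$genotype_format)
    pheno <- readr::read_csv(config$phenotype_path, show_col_types = FALSE, progress = FALSE)
  }

  qc <- qc_filter(
    geno,
    maf_min = config$qc$maf_min,
    snp_callrate_min = config$qc$snp_callrate_min,
    ind_callrate_min = config$qc$ind_callrate_min
  )
  geno <- qc$genotypes
  readr::write_csv(qc$report, file.path(out_dir, "qc_report.csv"), progress = FALSE)
  log_line("QC: %d -> %d SNPs", qc$report$n_snps_in, qc$report$n_snps_out)

  pvals <- NULL
  if (!is.null(config$pvalue_path)) {
    pvals <- readr::read_tsv(config$pvalue_path, show_col_types = FALSE, progress = FALSE)
    pvals <- pvals[pvals$snp_id %in% geno$snp_ids, , drop = FALSE]
  }

  # --- whole-data variance components per scenario --------------------
  spec <- config$spec
  design <- build_design(pheno, spec, individual_order = geno$individual_ids)
  pv_full <- pvals
  if (is.null(pv_full)) {
    log_line("running association scan on all records")
    pv_full <- run_ad_gwas(geno, pheno, covariates = spec$fixed_factors)
  }
  readr::write_tsv(
    pv_full[, c("snp_id", "chrom", "pos", "p_value")],
    file.path(out_dir, "pvalues.tsv"), progress = FALSE
  )

  comp_rows <- list()
  for (sc in config$scenarios) {
    fraction <- scenario_fraction(sc)
    if (is.na(fraction)) next
    log_line("scenario %s: partition fits", sc)
    part <- select_top_fraction(pv_full, fraction)
    G1 <- regularize(build_additive_grm(geno, part$prior_ids), config$ridge_factor)
    G2 <- regularize(build_additive_grm(geno, part$residual_ids), config$ridge_factor)
    D1 <- if (spec$include_dominance) {
      regularize(build_dominance_grm(geno, part$prior_ids), config$ridge_factor)
    }
    D2 <- if (spec$include_dominance) {
      regularize(build_dominance_grm(geno, part$residual_ids), config$ridge_factor)
    }
    pv_fit <- fit_partition_models(design, G1, G2, D1, D2, options = config$reml)
    wt <- build_weighted_set(G1, G2, pv_fit$tau, D1, D2)
    refit <- reml_estimate(design, wt$Gt, wt$Dt, options = config$reml)
    lab <- function(fit, set) {
      dplyr::mutate(tidy(fit), scenario = sc, matrix = set, tau_scenario = pv_fit$tau)
    }
    comp_rows[[sc]] <- dplyr::bind_rows(
      lab(pv_fit$fit_prior, "G1"),
      lab(pv_fit$fit_residual, "G2"),
      lab(refit, "Gt")
    )
  }
  components <- dplyr::bind_rows(comp_rows)
  if (nrow(components)) {
    readr::write_csv(components, file.path(out_dir, "variance_components.csv"),
                     progress = FALSE)
  }

  # --- cross-validation -----------------------------------------------
  folds <- assign_folds(geno$individual_ids, k = config$cv_k,
                        seed = derive_seed(config$seed, 31L))
  reports <- list()
  for (sc in config$scenarios) {
    log_line("scenario %s: %d-fold cross-validation", sc, config$cv_k)
    reports[[sc]] <- run_cv(
      geno, pheno,
      scenario = sc, pvals = pvals, spec = spec,
      seed = derive_seed(config$seed, 31L),
      options = config$reml, ridge_factor = config$ridge_factor,
      folds = folds
    )
  }
  cv_tab <- dplyr::bind_rows(lapply(reports, as_tibble))
  readr::write_csv(cv_tab, file.path(out_dir, "cv_report.csv"), progress = FALSE)
  comparison <- if (length(reports) >= 2) compare_scenarios(reports) else NULL
  if (!is.null(comparison)) {
    readr::write_csv(comparison$means, file.path(out_dir, "scenario_means.csv"),
                     progress = FALSE)
    readr::write_csv(comparison$anova, file.path(out_dir, "scenario_anova.csv"),
                     progress = FALSE)
  }
  if (!is.null(truth)) {
    readr::write_csv(truth, file.path(out_dir, "truth.csv"), progress = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gablup")),
    seed = config$seed,
    scenarios = config$scenarios,
    n_individuals = length(geno$individual_ids),
    n_snps = length(geno$snp_ids),
    n_records = nrow(pheno),
    cv_k = config$cv_k,
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line("done")
  invisible(list(
    components = components, reports = reports,
    comparison = comparison, manifest = manifest, out_dir = out_dir
  ))
}
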