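#' Assign individuals to cross-validation folds
#'
#' Uniform random partition of individuals (never records) into `k` folds of
#' sizes differing by at most one, deterministic for a given seed.
#'
#' @param individual_ids Character vector of ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A tibble with columns `individual_id`, `fold`; attributes `k` and
#'   `seed`.
#' @export
assign_folds <- function(individual_ids, k = 5L, seed = 1L) {
  n <- length(individual_ids)
  if (n < k) abort(sprintf("Need at least k = %d individuals, got %d.", k, n))
  if (anyDuplicated(individual_ids)) abort("Individual ids must be unique.")
  with_seed(seed, {
    shuffled <- sample(individual_ids)
    fold <- rep(seq_len(k), length.out = n)
    out <- tibble(individual_id = shuffled, fold = fold)
    out <- out[match(individual_ids, out$individual_id), ]
    attr(out, "k") <- as.integer(k)
    attr(out, "seed") <- as.integer(seed)
    out
  })
}

#' Fixed-effect-adjusted phenotypes
#'
#' Subtracts the fitted fixed-effect part (training estimates) from every
#' record and averages within individual. Records whose factor level was not
#' observed in training cannot be adjusted and are dropped with a warning.
#' These adjusted values are the validation response in cross-validation.
#'
#' @param pheno Record-level tibble.
#' @param fit An `mme_solution` (carries the training fixed-effect estimates
#'   and factor levels).
#' @return A tibble with columns `individual_id`, `adjusted`, `n_records`.
#' @export
adjusted_phenotypes <- function(pheno, fit) {
  if (!inherits(fit, "mme_solution")) abort("`fit` must come from solve_mme().")
  dat <- as_tibble(pheno)
  keep <- rep(TRUE, nrow(dat))
  for (f in names(fit$xlev)) {
    keep <- keep & (as.character(dat[[f]]) %in% fit$xlev[[f]])
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warn(sprintf(
      "%d records dropped: factor levels unseen in training.", n_dropped
    ))
    dat <- dat[keep, , drop = FALSE]
  }
  if (nrow(dat) == 0L) abort("No records left after dropping unseen levels.")
  for (f in names(fit$xlev)) {
    dat[[f]] <- factor(as.character(dat[[f]]), levels = fit$xlev[[f]])
  }
  Xn <- model.matrix(fit$formula, data = dat)
  Xn <- Xn[, names(fit$b_hat), drop = FALSE]
  adj <- dat$value - as.numeric(Xn %*% fit$b_hat)
  out <- tapply(adj, dat$individual_id, mean)
  cnt <- tapply(adj, dat$individual_id, length)
  tibble(
    individual_id = names(out),
    adjusted = as.numeric(out),
    n_records = as.integer(cnt)
  )
}

#' Prediction accuracy of genomic breeding values
#'
#' Two conventions are supported. The default, `cor_over_h`, is the
#' correlation between adjusted phenotypes and GEBVs divided by the square
#' root of the heritability (the usual predictive-ability-to-accuracy
#' rescaling). `literal_cov_over_h2` is the covariance of the two divided by
#' the heritability itself, a scale-dependent variant found in some
#' cross-validation write-ups; it is reported in parallel so either
#' convention can be compared.
#'
#' @param adjusted Per-individual adjusted phenotypes (validation).
#' @param gebv Matching genomic breeding values.
#' @param h2 Additive heritability used in the denominator (> 0).
#' @param method `"cor_over_h"` or `"literal_cov_over_h2"`.
#' @return A single accuracy value; `NA` (with a warning) when either vector
#'   has zero variance.
#' @export
prediction_accuracy <- function(adjusted, gebv, h2,
                                method = c("cor_over_h", "literal_cov_over_h2")) {
  method <- match.arg(method)
  ok <- is.finite(adjusted) & is.finite(gebv)
  adjusted <- adjusted[ok]
  gebv <- gebv[ok]
  if (length(adjusted) < 3) abort("Need at least 3 validation individuals.")
  stopifnot_scalar_number(h2, "h2")
  if (h2 <= 0) abort("`h2` must be positive.")
  if (sd(adjusted) == 0 || sd(gebv) == 0) {
    warn("Zero variance in adjusted phenotypes or GEBVs; accuracy undefined.")
    return(NA_real_)
  }
  if (method == "cor_over_h") {
    cor(adjusted, gebv) / sqrt(h2)
  } else {
    cov(adjusted, gebv) / h2
  }
}

scenario_fraction <- function(scenario) {
  if (is.numeric(scenario)) {
    if (scenario <= 0 || scenario >= 1) abort("Numeric scenario must be in (0, 1).")
    return(scenario)
  }
  switch(scenario,
    none = NA_real_,
    top5 = 0.05, top10 = 0.10, top15 = 0.15, top20 = 0.20,
    abort(sprintf("Unknown scenario '%s'.", scenario))
  )
}

#' Cross-validated genomic prediction accuracy for one prior scenario
#'
#' Five-fold (by default) cross-validation of GBLUP or GBLUP-GA prediction.
#' Per fold, validation phenotypes are masked and the full training-only
#' chain runs: (for prior scenarios) SNP partition by p-value, two
#' partition REML fits, the weight tau, the weighted matrices `Gt`/`Dt`, a
#' variance-component refit with the weighted matrices, then the mixed-model
#' equations with validation individuals unphenotyped but present in the
#' relationship matrix. Accuracy compares their fixed-effect-adjusted mean
#' phenotypes with their GEBVs. Scenario `"none"` is plain GBLUP with the
#' whole-panel matrices.
#'
#' When `pvals` is `NULL`, the association scan is recomputed inside each
#' training fold (leakage-free). Supplying `pvals` (e.g. from an external
#' GWAS on the full population) uses them as-is for every fold; a note marks
#' the potential leakage.
#'
#' @param geno A [genotype_matrix()] with complete codes.
#' @param pheno Record-level phenotype tibble.
#' @param scenario `"none"`, `"top5"`, `"top10"`, `"top15"`, `"top20"`, or a
#'   numeric prior fraction in (0, 1).
#' @param pvals Optional SNP p-value tibble (see [select_top_fraction()]).
#' @param spec A [model_spec()].
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @param options [reml_options()] for all REML fits.
#' @param ridge_factor Ridge applied to every matrix destined for inversion.
#' @param folds Optional precomputed [assign_folds()] table (shared across
#'   scenarios for paired comparisons).
#' @return A `cv_report` tibble with one row per fold: `scenario`, `fold`,
#'   `n_validation`, `accuracy` (cor-over-sqrt-h2), `accuracy_literal`,
#'   `raw_correlation`, `h2`, `tau`, `converged`.
#' @export
run_cv <- function(geno, pheno, scenario = "none", pvals = NULL,
                   spec = model_spec(), k = 5L, seed = 1L,
                   options = reml_options(), ridge_factor = 1e-6,
                   folds = NULL) {
  check_genotype_matrix(geno)
  fraction <- scenario_fraction(scenario)
  ids <- geno$individual_ids
  if (is.null(folds)) folds <- assign_folds(ids, k = k, seed = seed)
  k <- attr(folds, "k") %||% k
  has_d <- spec$include_dominance

  G_all <- regularize(build_additive_grm(geno), ridge_factor)
  D_all <- if (has_d) regularize(build_dominance_grm(geno), ridge_factor) else NULL

  fixed_partition <- NULL
  fixed_mats <- NULL
  if (!is.na(fraction) && !is.null(pvals)) {
    inform(paste(
      "Using supplied p-values for every fold; if they were computed on the",
      "full population the cross-validation is not leakage-free."
    ))
    fixed_partition <- select_top_fraction(pvals, fraction)
    # partition does not depend on the fold, so build its matrices once
    fixed_mats <- list(
      G1 = regularize(build_additive_grm(geno, fixed_partition$prior_ids), ridge_factor),
      G2 = regularize(build_additive_grm(geno, fixed_partition$residual_ids), ridge_factor),
      D1 = if (has_d) regularize(build_dominance_grm(geno, fixed_partition$prior_ids), ridge_factor),
      D2 = if (has_d) regularize(build_dominance_grm(geno, fixed_partition$residual_ids), ridge_factor)
    )
  }

  fold_ids <- sort(unique(folds$fold))
  rows <- vector("list", length(fold_ids))
  warm <- options
  for (fi in seq_along(fold_ids)) {
    f <- fold_ids[fi]
    val_ids <- folds$individual_id[folds$fold == f]
    pheno_train <- pheno[!(pheno$individual_id %in% val_ids), , drop = FALSE]
    pheno_val <- pheno[pheno$individual_id %in% val_ids, , drop = FALSE]
    design_train <- build_design(pheno_train, spec, individual_order = ids)

    tau <- NA_real_
    if (is.na(fraction)) {
      vc <- reml_estimate(design_train, G_all, D_all, options = warm)
      Gu <- G_all
      Du <- D_all
    } else {
      if (is.null(fixed_partition)) {
        pv_fold <- run_ad_gwas(geno, pheno_train, covariates = spec$fixed_factors)
        part <- select_top_fraction(pv_fold, fraction)
        G1 <- regularize(build_additive_grm(geno, part$prior_ids), ridge_factor)
        G2 <- regularize(build_additive_grm(geno, part$residual_ids), ridge_factor)
        D1 <- if (has_d) regularize(build_dominance_grm(geno, part$prior_ids), ridge_factor) else NULL
        D2 <- if (has_d) regularize(build_dominance_grm(geno, part$residual_ids), ridge_factor) else NULL
      } else {
        G1 <- fixed_mats$G1
        G2 <- fixed_mats$G2
        D1 <- fixed_mats$D1
        D2 <- fixed_mats$D2
      }
      pv_fit <- fit_partition_models(design_train, G1, G2, D1, D2, options = warm)
      tau <- pv_fit$tau
      wt <- build_weighted_set(G1, G2, tau, D1, D2)
      vc <- reml_estimate(design_train, wt$Gt, wt$Dt, options = warm)
      Gu <- wt$Gt
      Du <- wt$Dt
    }
    sol <- solve_mme(design_train, Gu, Du, vc)
    adj <- adjusted_phenotypes(pheno_val, sol)
    gebv <- sol$u_hat[adj$individual_id]
    h2 <- genetic_parameters(vc)$h2_additive
    rows[[fi]] <- tibble(
      scenario = as.character(scenario),
      fold = f,
      n_validation = length(val_ids),
      accuracy = prediction_accuracy(adj$adjusted, gebv, h2, "cor_over_h"),
      accuracy_literal = prediction_accuracy(adj$adjusted, gebv, h2, "literal_cov_over_h2"),
      raw_correlation = cor(adj$adjusted, gebv),
      h2 = h2,
      tau = tau,
      converged = vc$converged
    )
    # warm-start the next fold from this fold's estimates
    warm$init <- c(
      sigma_a2 = vc$sigma_a2, sigma_p2 = vc$sigma_p2,
      sigma_d2 = vc$sigma_d2, sigma_e2 = vc$sigma_e2
    )
    warm$init <- warm$init[!is.na(warm$init)]
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cv_report", class(out))
  attr(out, "scenario") <- as.character(scenario)
  attr(out, "k") <- k
  attr(out, "seed") <- attr(folds, "seed")
  attr(out, "method") <- "cor_over_h"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare prediction accuracy across prior-information scenarios
#'
#' One-way linear model of fold-level accuracy on scenario, with the
#' associated analysis of variance, mirroring the accuracy-versus-proportion
#' comparison used to judge whether prior marker information helps.
#'
#' @param reports A list of `cv_report`s (or a single tibble with `scenario`
#'   and `accuracy` columns covering at least two scenarios).
#' @return A `scenario_comparison` object: `anova` (term, df, sumsq, meansq,
#'   statistic, p.value), `means` (per-scenario mean, sd, n folds), and the
#'   underlying `lm` fit.
#' @export
compare_scenarios <- function(reports) {
  tab <- if (is.data.frame(reports)) as_tibble(reports) else dplyr::bind_rows(reports)
  if (!all(c("scenario", "accuracy") %in% names(tab))) {
    abort("Reports must have `scenario` and `accuracy` columns.")
  }
  if (length(unique(tab$scenario)) < 2) abort("Need at least two scenarios.")
  n_per <- table(tab$scenario)
  if (any(n_per < 2)) abort("Each scenario needs at least two folds.")
  fit <- lm(accuracy ~ scenario, data = tab)
  av <- anova(fit)
  anova_tab <- tibble(
    term = rownames(av),
    df = av$Df,
    sumsq = av$`Sum Sq`,
    meansq = av$`Mean Sq`,
    statistic = av$`F value`,
    p.value = av$`Pr(>F)`
  )
  means <- tab |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = sd(.data$accuracy),
      n_folds = dplyr::n(),
      .groups = "drop"
    )
  structure(
    list(anova = anova_tab, means = means, fit = fit),
    class = "scenario_comparison"
  )
}

#' @exportS3Method base::print
print.scenario_comparison <- function(x, ...) {
  cat("<scenario_comparison>\n")
  print(x$means)
  cat(sprintf(
    "F(%d, %d) = %.3f, p = %.4g\n",
    x$anova$df[1], x$anova$df[2], x$anova$statistic[1], x$anova$p.value[1]
  ))
  invisible(x)
}
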