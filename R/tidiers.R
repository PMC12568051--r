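#' Tidy a REML fit
#'
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimated component: `component`,
#'   `estimate`, `std.error`, `at_floor`.
#' @export
tidy.reml_fit <- function(x, ...) {
  est <- c(
    sigma_a2 = x$sigma_a2, sigma_p2 = x$sigma_p2,
    sigma_d2 = x$sigma_d2, sigma_e2 = x$sigma_e2
  )
  est <- est[x$components]
  tibble(
    component = x$components,
    estimate = unname(est),
    std.error = unname(x$standard_errors[x$components]),
    at_floor = x$components %in% x$pinned
  )
}

#' Glance at a REML fit
#'
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `converged`, `n_iterations`,
#'   `n_em_steps`, plus the genetic parameters `h2_additive`,
#'   `h2_dominance`, `repeatability`.
#' @export
glance.reml_fit <- function(x, ...) {
  gp <- genetic_parameters(x)
  tibble(
    logLik = x$loglik,
    converged = x$converged,
    n_iterations = x$n_iterations,
    n_em_steps = x$n_em_steps,
    h2_additive = gp$h2_additive,
    h2_dominance = gp$h2_dominance,
    repeatability = gp$repeatability
  )
}

#' Tidy the partition variance decomposition
#'
#' @param x A `partition_variances` from [fit_partition_models()].
#' @param ... Unused.
#' @return A tibble with one row per matrix set (prior/residual) and the
#'   additive and dominance genetic variances, plus the shared weight `tau`.
#' @export
tidy.partition_variances <- function(x, ...) {
  tibble(
    set = c("prior", "residual"),
    sigma_a2 = c(x$sigma_Ga1_2, x$sigma_Ga2_2),
    sigma_d2 = c(x$sigma_Gd1_2, x$sigma_Gd2_2),
    tau = c(x$tau, 1 - x$tau),
    converged = c(x$fit_prior$converged, x$fit_residual$converged)
  )
}

#' Glance at a partition variance decomposition
#'
#' @param x A `partition_variances`.
#' @param ... Unused.
#' @return A one-row tibble with `tau` and the four genetic variances.
#' @export
glance.partition_variances <- function(x, ...) {
  tibble(
    tau = x$tau,
    sigma_Ga1_2 = x$sigma_Ga1_2,
    sigma_Gd1_2 = x$sigma_Gd1_2,
    sigma_Ga2_2 = x$sigma_Ga2_2,
    sigma_Gd2_2 = x$sigma_Gd2_2,
    converged = x$converged
  )
}

#' Summarise a cross-validation report
#'
#' @param x A `cv_report` from [run_cv()].
#' @param ... Unused.
#' @return A one-row tibble: scenario, number of folds, mean and sd of the
#'   fold accuracies (both conventions), mean heritability and mean tau.
#' @export
glance.cv_report <- function(x, ...) {
  tibble(
    scenario = attr(x, "scenario"),
    k = attr(x, "k"),
    mean_accuracy = mean(x$accuracy),
    sd_accuracy = sd(x$accuracy),
    mean_accuracy_literal = mean(x$accuracy_literal),
    mean_h2 = mean(x$h2),
    mean_tau = mean(x$tau),
    all_converged = all(x$converged)
  )
}

#' Tidy a scenario comparison
#'
#' @param x A `scenario_comparison` from [compare_scenarios()].
#' @param ... Unused.
#' @return The ANOVA table as a tibble.
#' @export
tidy.scenario_comparison <- function(x, ...) x$anova

#' Glance at a scenario comparison
#'
#' @param x A `scenario_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with the F statistic and p-value.
#' @export
glance.scenario_comparison <- function(x, ...) {
  tibble(
    statistic = x$anova$statistic[1],
    p.value = x$anova$p.value[1],
    df = x$anova$df[1],
    df.residual = x$anova$df[2]
  )
}
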