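#' Plot fold accuracies of a cross-validation report
#'
#' Bar of the mean fold accuracy with the individual folds overplotted.
#'
#' @param object A `cv_report` from [run_cv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$accuracy)) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey70", width = 0.6) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      x = "prior marker information", y = "prediction accuracy",
      title = sprintf("%d-fold cross-validated accuracy", attr(object, "k"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot mean accuracy by prior-information scenario
#'
#' Mean fold accuracy per scenario with one-SD error bars, the layout used to
#' compare prior-information proportions.
#'
#' @param object A `scenario_comparison` from [compare_scenarios()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scenario_comparison <- function(object, ...) {
  m <- object$means
  ggplot2::ggplot(m, ggplot2::aes(x = .data$scenario, y = .data$mean_accuracy)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_accuracy - .data$sd_accuracy,
        ymax = .data$mean_accuracy + .data$sd_accuracy
      ),
      width = 0.2
    ) +
    ggplot2::labs(x = "prior marker information", y = "mean prediction accuracy") +
    ggplot2::theme_minimal()
}

#' Quick association-scan plot
#'
#' -log10 p-values along the genome from [run_ad_gwas()].
#'
#' @param pvals A p-value tibble (`snp_id`, `chrom`, `pos`, `p_value`).
#' @return A ggplot object.
#' @export
plot_gwas <- function(pvals) {
  df <- as_tibble(pvals)
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$index, y = -log10(.data$p_value),
    colour = factor(.data$chrom %% 2)
  )) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::labs(x = "SNP index", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
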