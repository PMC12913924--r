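#' BIC trace plot for a clustering fit
#'
#' @param object A [twostep_cluster()] fit.
#' @param ... Unused.
#' @return A ggplot: BIC against cluster count, selected k marked.
#' @export
autoplot.twostep_cluster <- function(object, ...) {
  df <- dplyr::filter(object$bic, !is.na(.data$bic))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(
      x = "number of clusters", y = "BIC",
      title = sprintf("Two-step clustering: k = %d selected", object$k)
    )
}

#' Threshold-selection traces for a LOGO fit
#'
#' @param object A [run_logo()] fit.
#' @param ... Unused.
#' @return A ggplot of incremental R^2 against p-value threshold per fold.
#' @export
autoplot.logo_fit <- function(object, ...) {
  tr <- purrr::imap_dfr(object$models, function(m, i) {
    dplyr::mutate(m$trace, fold = factor(i))
  })
  ggplot2::ggplot(
    dplyr::filter(tr, !is.na(.data$r2)),
    ggplot2::aes(
      x = .data$threshold, y = .data$r2,
      colour = .data$fold, group = .data$fold
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "p-value threshold", y = "held-out incremental R²",
      colour = "fold"
    )
}

#' Score-versus-phenotype scatter plot
#'
#' @param scores Tibble with `sample` and `ige_prs_z` (e.g. from
#'   [zscore_reference()]).
#' @param cohort Cohort tibble with `sample` and `log_ige`.
#' @return A ggplot with the least-squares line.
#' @export
plot_score_phenotype <- function(scores, cohort) {
  df <- dplyr::inner_join(scores, cohort, by = "sample")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ige_prs_z, y = .data$log_ige)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(
      x = "IgE polygenic score (z)",
      y = expression(log[10] ~ "total IgE (IU/mL)")
    )
}
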