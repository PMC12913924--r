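#' Tidy a two-step clustering fit
#'
#' @param x A [twostep_cluster()] object.
#' @param ... Unused.
#' @return One row per cluster: `cluster`, `n`, and the standardized
#'   center coordinate for each feature.
#' @export
tidy.twostep_cluster <- function(x, ...) {
  sizes <- table(factor(x$labels$cluster, levels = seq_len(x$k)))
  dplyr::bind_cols(
    tibble::tibble(cluster = seq_len(x$k), n = as.integer(sizes)),
    tibble::as_tibble(x$centers)
  )
}

#' @rdname tidy.twostep_cluster
#' @export
glance.twostep_cluster <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = x$n, silhouette = x$silhouette,
    bic_min = min(x$bic$bic, na.rm = TRUE),
    n_preclusters = x$n_preclusters, n_dropped = x$n_dropped
  )
}

#' Tidy a LOGO PRS fit
#'
#' @param x A [run_logo()] object.
#' @param ... Unused.
#' @return The per-fold table: base/target sizes, chosen threshold, SNP
#'   count, out-of-sample SE and held-out incremental R^2.
#' @export
tidy.logo_fit <- function(x, ...) x$folds

#' @rdname tidy.logo_fit
#' @export
glance.logo_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = nrow(x$scores),
    mean_snps = mean(x$folds$n_snps),
    mean_r2_holdout = mean(x$folds$r2_holdout)
  )
}

#' Tidy a PRS model
#'
#' @param x A [prs_model()].
#' @param ... Unused.
#' @return The SNP weight table.
#' @export
tidy.prs_model <- function(x, ...) x$snps

#' @rdname tidy.prs_model
#' @export
glance.prs_model <- function(x, ...) {
  tibble::tibble(
    n_snps = nrow(x$snps), threshold = x$threshold, fold = x$fold
  )
}

#' Tidy a centroid model
#'
#' @param x A `centroid_model`.
#' @param ... Unused.
#' @return Long tibble: `cluster`, `feature`, `center` (standardized).
#' @export
tidy.centroid_model <- function(x, ...) {
  tibble::as_tibble(x$centroids) |>
    dplyr::mutate(cluster = dplyr::row_number()) |>
    tidyr::pivot_longer(-"cluster", names_to = "feature", values_to = "center")
}
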