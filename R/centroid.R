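#' Fit cluster centroids for nearest-centroid classification
#'
#' Centroids are per-cluster means in standardized feature space. By
#' default the standardization (per-feature mean and SD) is inherited from
#' a clustering build so new cases are projected into exactly the space the
#' clusters were formed in; otherwise it is computed from `features`.
#'
#' @param features Data frame of the clustering variables (optionally with
#'   a `sample` column).
#' @param labels Cluster labels, one per row; every cluster must be
#'   non-empty (trivially true) and labels must be positive integers.
#' @param standardization Optional list(`mean`, `sd`, `features`) as stored
#'   in a [twostep_cluster()] fit.
#' @return An object of class `centroid_model`.
#' @export
fit_centroids <- function(features, labels, standardization = NULL) {
  df <- as.data.frame(features)
  num <- dplyr::select(df, dplyr::where(is.numeric))
  num <- dplyr::select(num, -dplyr::any_of("cluster_truth"))
  x <- as.matrix(num)
  if (nrow(x) != length(labels)) abort("`labels` must match rows of `features`.")
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  if (!identical(ks, seq_len(max(ks))))
    abort(paste0("empty cluster(s): labels must cover 1..k, got ", paste(ks, collapse = ",")))
  if (is.null(standardization)) {
    # population (ML) SD: invariant under duplicating the dataset
    standardization <- list(
      mean = colMeans(x),
      sd = apply(x, 2, function(v) sqrt(mean((v - mean(v))^2))),
      features = colnames(x)
    )
  }
  if (!identical(colnames(x), standardization$features))
    abort("feature columns must match the standardization's features.")
  if (any(standardization$sd == 0)) abort("zero-SD feature in standardization.")
  xs <- sweep(sweep(x, 2, standardization$mean), 2, standardization$sd, "/")
  cent <- matrix(NA_real_, length(ks), ncol(x),
    dimnames = list(NULL, colnames(x))
  )
  for (g in ks) cent[g, ] <- colMeans(xs[labels == g, , drop = FALSE])
  structure(
    list(centroids = cent, standardization = standardization),
    class = "centroid_model"
  )
}

#' Extract the centroid model from a clustering fit
#'
#' @param fit A [twostep_cluster()] object.
#' @return A `centroid_model` sharing the fit's standardization.
#' @export
as_centroid_model <- function(fit) {
  stopifnot(inherits(fit, "twostep_cluster"))
  structure(
    list(centroids = fit$centers, standardization = fit$standardization),
    class = "centroid_model"
  )
}

#' @export
print.centroid_model <- function(x, ...) {
  cat(sprintf(
    "<centroid_model> %d clusters x %d features\n",
    nrow(x$centroids), ncol(x$centroids)
  ))
  invisible(x)
}

#' Nearest-centroid assignment
#'
#' Standardizes the input with the model's stored parameters and assigns
#' each complete row to the cluster whose centroid is closest in Euclidean
#' distance; ties go to the lowest cluster index. Rows with any missing
#' feature are reported unassigned (`NA`).
#'
#' @param model A `centroid_model`.
#' @param features Data frame with the model's feature columns (optionally
#'   a `sample` column for ids).
#' @return A tibble: `sample`, `cluster`, and one `dist_<g>` column per
#'   cluster.
#' @export
assign_nearest <- function(model, features) {
  stopifnot(inherits(model, "centroid_model"))
  if (nrow(model$centroids) == 0) abort("empty centroid model.")
  df <- as.data.frame(features)
  ids <- if ("sample" %in% names(df)) as.character(df$sample) else as.character(seq_len(nrow(df)))
  miss_cols <- setdiff(model$standardization$features, names(df))
  if (length(miss_cols))
    abort(paste0("missing feature column(s): ", paste(miss_cols, collapse = ", ")))
  x <- as.matrix(df[model$standardization$features])
  xs <- sweep(sweep(x, 2, model$standardization$mean), 2,
    model$standardization$sd, "/"
  )
  k <- nrow(model$centroids)
  dists <- matrix(NA_real_, nrow(xs), k)
  for (g in seq_len(k)) {
    dists[, g] <- sqrt(rowSums(sweep(xs, 2, model$centroids[g, ])^2))
  }
  complete <- complete.cases(x)
  if (any(!complete))
    inform(paste0("assign_nearest: ", sum(!complete), " row(s) with missing features left unassigned."))
  cluster <- rep(NA_integer_, nrow(xs))
  cluster[complete] <- apply(
    dists[complete, , drop = FALSE], 1,
    function(v) which(v <= min(v) + 1e-12)[1]
  )
  colnames(dists) <- paste0("dist_", seq_len(k))
  tibble::tibble(sample = ids, cluster = cluster, !!!as.data.frame(dists))
}
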