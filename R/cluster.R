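# Log-likelihood "distance" machinery for two-step clustering, continuous
# features only. Each cluster v contributes
#   xi_v = -N_v * sum_d 0.5 * log(gvar_d + var_vd)
# where var_vd is the within-cluster ML variance and gvar_d the whole-sample
# variance of feature d (the regularizer that keeps log() finite for tight
# clusters). The distance between clusters is the loss of total xi when they
# are merged: d(a, b) = xi_a + xi_b - xi_{a+b}.

.xi_of <- function(n, s, ss, gvar) {
  v <- pmax(ss / n - (s / n)^2, 0)
  -n * sum(0.5 * log(gvar + v))
}

# vectorized: xi of each row-cluster in (n, S, SS) matrices
.xi_rows <- function(n, S, SS, gvar) {
  v <- pmax(SS / n - (S / n)^2, 0)
  -n * rowSums(0.5 * log(sweep(v, 2, gvar, "+")))
}

# stage 1: sequential preclustering with threshold growth. Points are
# assigned to the nearest precluster if the merge distance is within the
# threshold, else start a new one; when the leaf budget is exceeded the
# threshold grows and the pass restarts.
.precluster <- function(x, gvar, max_leaves) {
  n <- nrow(x)
  d <- ncol(x)
  xi_single <- -sum(0.5 * log(gvar)) # xi of any singleton
  threshold <- 0
  repeat {
    S <- matrix(0, 0, d)
    SS <- matrix(0, 0, d)
    cn <- numeric(0)
    xi <- numeric(0)
    assign <- integer(n)
    overflow <- FALSE
    for (i in seq_len(n)) {
      if (length(cn) > 0) {
        nm <- cn + 1
        Sm <- sweep(S, 2, x[i, ], "+")
        SSm <- sweep(SS, 2, x[i, ]^2, "+")
        xim <- .xi_rows(nm, Sm, SSm, gvar)
        dist <- xi + xi_single - xim
        j <- which.min(dist)
      } else {
        j <- NA_integer_
      }
      if (!is.na(j) && dist[j] <= threshold) {
        cn[j] <- cn[j] + 1
        S[j, ] <- S[j, ] + x[i, ]
        SS[j, ] <- SS[j, ] + x[i, ]^2
        xi[j] <- .xi_of(cn[j], S[j, ], SS[j, ], gvar)
        assign[i] <- j
      } else {
        S <- rbind(S, x[i, , drop = FALSE])
        SS <- rbind(SS, x[i, , drop = FALSE]^2)
        cn <- c(cn, 1)
        xi <- c(xi, xi_single)
        assign[i] <- length(cn)
      }
      if (length(cn) > max_leaves) {
        overflow <- TRUE
        break
      }
    }
    if (!overflow) {
      return(list(assign = assign, n = cn, S = S, SS = SS, xi = xi))
    }
    # grow the threshold to the scale of the closest current pair and retry
    pd <- .pairwise_lldist(cn, S, SS, xi, gvar)
    min_d <- min(pd[upper.tri(pd)])
    threshold <- max(threshold * 2, min_d * 2, 1e-8)
  }
}

.pairwise_lldist <- function(cn, S, SS, xi, gvar) {
  J <- length(cn)
  out <- matrix(Inf, J, J)
  for (a in seq_len(J - 1)) {
    bs <- (a + 1):J
    nm <- cn[a] + cn[bs]
    Sm <- sweep(S[bs, , drop = FALSE], 2, S[a, ], "+")
    SSm <- sweep(SS[bs, , drop = FALSE], 2, SS[a, ], "+")
    xim <- .xi_rows(nm, Sm, SSm, gvar)
    out[a, bs] <- out[bs, a] <- xi[a] + xi[bs] - xim
  }
  out
}

# stage 2: greedy agglomeration of preclusters by log-likelihood distance.
# Returns merge distances (k clusters -> k-1) and precluster->cluster maps
# for every k from J down to 1.
.agglomerate <- function(cn, S, SS, xi, gvar) {
  J <- length(cn)
  active <- rep(TRUE, J)
  member <- as.list(seq_len(J)) # preclusters in each active cluster
  maps <- vector("list", J)
  map_now <- seq_len(J)
  maps[[J]] <- map_now
  dmat <- .pairwise_lldist(cn, S, SS, xi, gvar)
  diag(dmat) <- Inf
  merge_dist <- rep(NA_real_, J) # index k: distance merging k -> k-1
  for (k in J:2) {
    idx <- which(active)
    sub <- dmat[idx, idx, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    a <- idx[min(best)]
    b <- idx[max(best)]
    merge_dist[k] <- dmat[a, b]
    # merge b into a
    cn[a] <- cn[a] + cn[b]
    S[a, ] <- S[a, ] + S[b, ]
    SS[a, ] <- SS[a, ] + SS[b, ]
    xi[a] <- .xi_of(cn[a], S[a, ], SS[a, ], gvar)
    active[b] <- FALSE
    member[[a]] <- c(member[[a]], member[[b]])
    map_now[member[[a]]] <- a
    rest <- setdiff(which(active), a)
    if (length(rest)) {
      nm <- cn[a] + cn[rest]
      Sm <- sweep(S[rest, , drop = FALSE], 2, S[a, ], "+")
      SSm <- sweep(SS[rest, , drop = FALSE], 2, SS[a, ], "+")
      xim <- .xi_rows(nm, Sm, SSm, gvar)
      dd <- xi[a] + xi[rest] - xim
      dmat[a, rest] <- dmat[rest, a] <- dd
    }
    dmat[b, ] <- dmat[, b] <- Inf
    # snapshot map at k-1 clusters, renumbered 1..k-1 by first appearance
    mp <- map_now
    maps[[k - 1]] <- match(mp, unique(mp))
  }
  # renumber all snapshots consistently
  maps <- lapply(maps, function(mp) match(mp, unique(mp)))
  list(merge_dist = merge_dist, maps = maps)
}

#' BIC of a clustering under the two-step Gaussian model
#'
#' `BIC(k) = -2 * sum_v xi_v + 2 k d log N`, where each cluster's
#' log-likelihood term uses per-feature Gaussian variances regularized by
#' the whole-sample variance, and `2 k d` counts one mean and one variance
#' per cluster and feature.
#'
#' @param features Numeric data frame / matrix (complete cases).
#' @param labels Integer cluster labels, one per row.
#' @param standardize Z-score columns first (default `TRUE`, matching
#'   [twostep_cluster()]).
#' @return The BIC value (single number).
#' @export
twostep_bic <- function(features, labels, standardize = TRUE) {
  x <- as.matrix(dplyr::select(as.data.frame(features), dplyr::where(is.numeric)))
  if (standardize) {
    mu <- colMeans(x)
    sds <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2)))
    x <- sweep(sweep(x, 2, mu), 2, sds, "/")
  }
  gvar <- apply(x, 2, function(v) mean((v - mean(v))^2))
  ll <- 0
  for (g in unique(labels)) {
    xs <- x[labels == g, , drop = FALSE]
    ll <- ll + .xi_of(nrow(xs), colSums(xs), colSums(xs^2), gvar)
  }
  -2 * ll + 2 * length(unique(labels)) * ncol(x) * log(nrow(x))
}

#' Two-step clustering with automatic cluster count
#'
#' Model-based clustering in the style of the classic two-step procedure:
#' features are standardized; stage 1 builds preclusters by sequential
#' log-likelihood-distance assignment under a growing distance threshold;
#' stage 2 agglomerates the preclusters by log-likelihood distance.
#' `BIC(k)` is computed along the merge path for `k = 1..k_max`. The
#' cluster count is chosen automatically: a coarse pass finds the smallest
#' k whose BIC-change ratio (relative to the first change) falls below
#' 0.04, then the ratio of successive merge distances refines the choice,
#' accepting the larger-k of the top two candidates when their ratios
#' differ by less than 15%. Cluster labels are renumbered in descending
#' order of the mean of the first feature (by convention the genetic
#' score), and rows with any missing feature are dropped with a message.
#'
#' @param features Data frame with the clustering variables, in order
#'   (first = genetic score). An optional `sample` column provides ids;
#'   non-numeric columns are otherwise ignored.
#' @param k_max Largest cluster count considered (default 15).
#' @param seed Seed controlling the stage-1 presentation order.
#' @param max_leaves Precluster budget for stage 1 (default 100).
#' @param k_select Optional fixed cluster count; skips the automatic rule
#'   and cuts the merge path at this k.
#' @return An object of class `twostep_cluster`: selected `k`, `labels`
#'   (tibble `sample`, `cluster`), standardized per-cluster `centers` and
#'   `variances`, the `standardization` (feature means/SDs), `bic` trace,
#'   `merge_distances`, the mean `silhouette` of the selected solution, and
#'   `n_dropped`.
#' @export
twostep_cluster <- function(features, k_max = 15L, seed = 1L,
                            max_leaves = 100L, k_select = NULL) {
  if (k_max < 1) abort("`k_max` must be >= 1.")
  df <- as.data.frame(features)
  ids <- if ("sample" %in% names(df)) as.character(df$sample) else as.character(seq_len(nrow(df)))
  num <- dplyr::select(df, dplyr::where(is.numeric))
  num <- dplyr::select(num, -dplyr::any_of("cluster_truth"))
  if (ncol(num) < 1) abort("no numeric feature columns found.")
  cc <- complete.cases(num)
  n_dropped <- sum(!cc)
  if (n_dropped > 0)
    inform(paste0("twostep_cluster: dropped ", n_dropped, " row(s) with missing features."))
  x_raw <- as.matrix(num[cc, , drop = FALSE])
  ids <- ids[cc]
  n <- nrow(x_raw)
  if (n < 4) abort("need at least 4 complete rows.")
  if (n < k_max) abort("fewer complete rows than `k_max`.")
  mu <- colMeans(x_raw)
  sds <- apply(x_raw, 2, function(v) sqrt(mean((v - mean(v))^2)))
  if (any(sds == 0)) abort("constant feature column(s); cannot standardize.")
  x <- sweep(sweep(x_raw, 2, mu), 2, sds, "/")
  gvar <- apply(x, 2, function(v) mean((v - mean(v))^2))
  ord <- withr::with_seed(seed, sample(n))
  pre <- .precluster(x[ord, , drop = FALSE], gvar, max_leaves)
  assign_pre <- integer(n)
  assign_pre[ord] <- pre$assign
  agg <- .agglomerate(pre$n, pre$S, pre$SS, pre$xi, gvar)
  J <- length(pre$n)
  d <- ncol(x)
  bic <- rep(NA_real_, k_max)
  for (k in seq_len(min(k_max, J))) {
    mp <- agg$maps[[k]]
    ll <- 0
    for (g in seq_len(k)) {
      pc <- which(mp == g)
      ll <- ll + .xi_of(
        sum(pre$n[pc]), colSums(pre$S[pc, , drop = FALSE]),
        colSums(pre$SS[pc, , drop = FALSE]), gvar
      )
    }
    bic[k] <- -2 * ll + 2 * k * d * log(n)
  }
  k_sel <- if (!is.null(k_select)) {
    if (k_select > J) abort("`k_select` exceeds the number of preclusters.")
    as.integer(k_select)
  } else {
    .auto_k(bic, agg$merge_dist, min(k_max, J))
  }
  mp <- agg$maps[[k_sel]]
  labels <- mp[assign_pre]
  # relabel in descending order of the first feature's mean
  means1 <- vapply(seq_len(k_sel), function(g) mean(x_raw[labels == g, 1]), numeric(1))
  relab <- match(labels, order(means1, decreasing = TRUE))
  centers <- matrix(NA_real_, k_sel, d, dimnames = list(NULL, colnames(x)))
  vars <- centers
  for (g in seq_len(k_sel)) {
    xs <- x[relab == g, , drop = FALSE]
    centers[g, ] <- colMeans(xs)
    vars[g, ] <- apply(xs, 2, function(v) mean((v - mean(v))^2))
  }
  sil <- if (k_sel >= 2) {
    silhouette_index(
      as.data.frame(x), relab,
      standardize = FALSE
    )
  } else {
    NA_real_
  }
  structure(
    list(
      k = k_sel,
      labels = tibble::tibble(sample = ids, cluster = relab),
      centers = centers, variances = vars,
      standardization = list(mean = mu, sd = sds, features = colnames(x)),
      bic = tibble::tibble(k = seq_len(k_max), bic = bic),
      merge_distances = tibble::tibble(
        k = seq_along(agg$merge_dist), distance = agg$merge_dist
      ),
      silhouette = sil, n_dropped = n_dropped, n = n,
      n_preclusters = J, seed = seed
    ),
    class = "twostep_cluster"
  )
}

# automatic cluster count: coarse BIC-change pass then merge-distance
# ratio refinement (two-candidates rule)
.auto_k <- function(bic, merge_dist, k_avail) {
  if (k_avail < 2) return(1L)
  dbic <- diff(bic[seq_len(k_avail)]) # dbic[k] = BIC(k+1) - BIC(k)
  if (is.na(dbic[1]) || dbic[1] >= 0) return(1L)
  ratio <- dbic / dbic[1]
  below <- which(ratio < 0.04)
  k_init <- if (length(below)) below[1] else k_avail
  if (k_init < 2) return(1L)
  # merge_dist[k] = distance merging k clusters -> k-1; candidates 2..k_init
  cand <- 2:k_init
  r <- merge_dist[cand] / merge_dist[cand + 1]
  r[!is.finite(r)] <- 0
  # homogeneity gate: accept a cluster structure only when the best merge
  # jump at least doubles the next merge distance; a smooth merge profile
  # (ratios near 1 everywhere) is what homogeneous data produce
  if (max(r) < 2) return(1L)
  if (length(cand) == 1) return(cand)
  ord <- order(r, decreasing = TRUE)
  top <- cand[ord[1]]
  second <- cand[ord[2]]
  if (r[ord[2]] <= 0 || r[ord[1]] / r[ord[2]] > 1.15) {
    as.integer(top)
  } else {
    as.integer(max(top, second))
  }
}

#' @export
print.twostep_cluster <- function(x, ...) {
  cat(sprintf(
    "<twostep_cluster> k = %d (of up to %d), n = %d, silhouette = %s\n",
    x$k, max(x$bic$k), x$n,
    ifelse(is.na(x$silhouette), "NA", sprintf("%.3f", x$silhouette))
  ))
  invisible(x)
}

#' Mean silhouette index
#'
#' Mean silhouette coefficient over samples using Euclidean distance on
#' (optionally standardized) features. Members of singleton clusters
#' contribute 0 by convention.
#'
#' @param features Numeric data frame / matrix (complete rows).
#' @param labels Cluster labels, one per row (at least 2 clusters).
#' @param standardize Z-score columns first (default `TRUE`).
#' @return The mean silhouette value in `[-1, 1]`.
#' @export
silhouette_index <- function(features, labels, standardize = TRUE) {
  x <- as.matrix(dplyr::select(as.data.frame(features), dplyr::where(is.numeric)))
  if (nrow(x) != length(labels)) abort("`labels` must match rows of `features`.")
  if (length(unique(labels)) < 2)
    abort("silhouette needs at least 2 clusters.")
  if (standardize) x <- scale(x)
  dm <- as.matrix(dist(x))
  n <- nrow(x)
  labs <- unique(labels)
  sizes <- table(factor(labels, levels = labs))
  s <- numeric(n)
  for (i in seq_len(n)) {
    li <- labels[i]
    if (sizes[[as.character(li)]] == 1) {
      s[i] <- 0
      next
    }
    a <- sum(dm[i, labels == li]) / (sizes[[as.character(li)]] - 1)
    b <- min(vapply(
      setdiff(labs, li),
      function(l) mean(dm[i, labels == l]), numeric(1)
    ))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
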