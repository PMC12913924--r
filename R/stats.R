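#' Pearson chi-square test of independence
#'
#' Pearson chi-square without continuity correction on an r x c count
#' table, `df = (r-1)(c-1)`, upper-tail p. Zero-margin rows or columns are
#' an error naming the offending margin.
#'
#' @param table Matrix of non-negative counts (at least 2x2).
#' @return A one-row tibble: `statistic`, `df`, `p`.
#' @export
chi_square_independence <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) abort("counts must be non-negative integers.")
  if (nrow(m) < 2 || ncol(m) < 2) abort("table must be at least 2x2.")
  rs <- rowSums(m)
  cs <- colSums(m)
  if (any(rs == 0)) abort(paste0("zero margin in row ", which(rs == 0)[1], "."))
  if (any(cs == 0)) abort(paste0("zero margin in column ", which(cs == 0)[1], "."))
  e <- outer(rs, cs) / sum(m)
  stat <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  tibble::tibble(
    statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE)
  )
}

.as_group_list <- function(groups) {
  if (!is.list(groups)) abort("`groups` must be a list of numeric vectors.")
  if (is.null(names(groups))) names(groups) <- as.character(seq_along(groups))
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (any(vapply(groups, length, integer(1)) == 0)) abort("empty group.")
  groups
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with p from the chi-square distribution on
#' k - 1 degrees of freedom. Invariant to monotone transforms of the data.
#'
#' @param groups List of numeric vectors, one per group.
#' @return A one-row tibble: `statistic`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- .as_group_list(groups)
  if (length(groups) < 2) abort("need at least 2 groups.")
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kt <- kruskal.test(unlist(groups, use.names = FALSE), g)
  tibble::tibble(
    statistic = unname(kt$statistic), df = unname(kt$parameter),
    p = kt$p.value
  )
}

#' Dunn pairwise post-hoc comparisons with Bonferroni adjustment
#'
#' Dunn's z on mean ranks with the tie-corrected pooled variance
#' `(N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_i + 1/n_j)`; raw two-sided
#' p-values are multiplied by the number of pairs and capped at 1.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups).
#' @return A tibble with one row per pair: `group1`, `group2`, `z`, `p`,
#'   `p_adj`.
#' @export
dunn_bonferroni <- function(groups) {
  groups <- .as_group_list(groups)
  k <- length(groups)
  if (k < 2) abort("need at least 2 groups.")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  mean_r <- tapply(r, factor(g, levels = names(groups)), mean)
  n_g <- lengths(groups)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2)
  n_pairs <- ncol(pairs)
  out <- purrr::map_dfr(seq_len(n_pairs), function(i) {
    g1 <- pairs[1, i]
    g2 <- pairs[2, i]
    se <- sqrt(v0 * (1 / n_g[[g1]] + 1 / n_g[[g2]]))
    z <- (mean_r[[g1]] - mean_r[[g2]]) / se
    p <- 2 * pnorm(-abs(z))
    tibble::tibble(
      group1 = g1, group2 = g2, z = z, p = p,
      p_adj = pmin(1, p * n_pairs)
    )
  })
  out
}

#' Covariate-adjusted two-group comparison
#'
#' Least-squares fit of `y ~ group + covariates` over complete cases
#' (listwise deletion, count reported); the returned effect is the group
#' coefficient.
#'
#' @param y Numeric outcome.
#' @param group Binary (0/1 or logical) group indicator.
#' @param covariates Optional data frame of covariates.
#' @return A one-row tibble: `beta`, `se`, `p`, `n_used`, `n_dropped`.
#' @export
adjusted_group_comparison <- function(y, group, covariates = NULL) {
  group <- as.numeric(group)
  n <- length(y)
  wmat <- .covariate_design(covariates, n)
  dat <- cbind(y = y, group = group, wmat)
  cc <- complete.cases(dat)
  if (sum(!cc) > 0)
    inform(paste0("adjusted_group_comparison: dropped ", sum(!cc), " incomplete row(s)."))
  x <- cbind(1, group = group[cc], wmat[cc, , drop = FALSE])
  .check_collinear(x)
  yy <- y[cc]
  fit <- stats::lm.fit(x, yy)
  df <- sum(cc) - ncol(x)
  s2 <- sum(fit$residuals^2) / df
  xtx_inv <- chol2inv(chol(crossprod(x)))
  beta <- fit$coefficients[["group"]]
  se <- sqrt(s2 * xtx_inv[2, 2])
  tibble::tibble(
    beta = beta, se = se, p = 2 * pt(-abs(beta / se), df),
    n_used = sum(cc), n_dropped = sum(!cc)
  )
}

#' Squared Pearson correlation with p-value
#'
#' @param x,y Numeric vectors (n >= 3, both non-constant).
#' @return A one-row tibble: `r`, `r2`, `p` (t transform, n - 2 df).
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  cc <- complete.cases(x, y)
  x <- x[cc]
  y <- y[cc]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input.")
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  tibble::tibble(r = r, r2 = r^2, p = 2 * pt(-abs(tstat), n - 2))
}

#' Parametric-vs-nonparametric routing gate
#'
#' Returns `"parametric"` only when no group rejects the Shapiro-Wilk
#' normality test at `alpha` and a mean-centered Levene test (one-way
#' ANOVA on absolute deviations from group means) does not reject;
#' otherwise `"nonparametric"`. Groups too small for the normality test
#' (n < 3) route to `"nonparametric"` with a reason.
#'
#' @param groups List of numeric vectors.
#' @param alpha Significance level for both tests (default 0.05).
#' @return A one-row tibble: `decision`, `reason`, `shapiro_min_p`,
#'   `levene_p`.
#' @export
normality_variance_gate <- function(groups, alpha = 0.05) {
  groups <- .as_group_list(groups)
  if (any(lengths(groups) < 3)) {
    return(tibble::tibble(
      decision = "nonparametric",
      reason = "group too small for normality test",
      shapiro_min_p = NA_real_, levene_p = NA_real_
    ))
  }
  sw <- vapply(groups, function(v) {
    if (length(v) > 5000) v <- sample(v, 5000)
    shapiro.test(v)$p.value
  }, numeric(1))
  absdev <- unlist(lapply(groups, function(v) abs(v - mean(v))), use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  lev <- oneway.test(absdev ~ g, var.equal = TRUE)
  lev_p <- lev$p.value
  if (min(sw) < alpha) {
    return(tibble::tibble(
      decision = "nonparametric", reason = "normality rejected",
      shapiro_min_p = min(sw), levene_p = lev_p
    ))
  }
  if (lev_p < alpha) {
    return(tibble::tibble(
      decision = "nonparametric", reason = "variance homogeneity rejected",
      shapiro_min_p = min(sw), levene_p = lev_p
    ))
  }
  tibble::tibble(
    decision = "parametric", reason = NA_character_,
    shapiro_min_p = min(sw), levene_p = lev_p
  )
}
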