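# Independent reference implementations used as oracles; deliberately
# written with different machinery than the package code paths.

# exact HWE by direct evaluation of the conditional distribution using
# plain factorials (valid for n <= 50, where 2n <= 100 < 171)
hwe_enum_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n1 <- 2 * min(n_aa, n_bb) + n_ab
  if (n1 == 0) return(1)
  hs <- seq(n1 %% 2, n1, by = 2)
  pr <- vapply(hs, function(h) {
    hom_rare <- (n1 - h) / 2
    hom_common <- (2 * n - n1 - h) / 2
    factorial(n) / (factorial(hom_rare) * factorial(h) * factorial(hom_common)) * 2^h
  }, numeric(1))
  pr <- pr / sum(pr)
  p_obs <- pr[hs == n_ab]
  sum(pr[pr <= p_obs * (1 + 1e-12)])
}

# brute-force greedy LD selection: literal restatement with nested loops
greedy_select_oracle <- function(stats, genotypes, p_max, r2_max, window_kb,
                                 strict = FALSE) {
  s <- stats[!is.na(stats$p), ]
  s <- if (strict) s[s$p < p_max, ] else s[s$p <= p_max, ]
  s <- s[order(s$p, s$pos, s$snp), ]
  d <- genotypes$dosage
  removed <- character()
  keep <- character()
  while (nrow(s) > 0) {
    lead <- s[1, ]
    keep <- c(keep, lead$snp)
    s <- s[-1, , drop = FALSE]
    if (nrow(s) == 0) break
    drop <- logical(nrow(s))
    for (i in seq_len(nrow(s))) {
      if (s$chr[i] == lead$chr && abs(s$pos[i] - lead$pos) <= window_kb * 1000) {
        r <- suppressWarnings(
          cor(d[, lead$snp], d[, s$snp[i]], use = "pairwise.complete.obs")
        )
        r2 <- ifelse(is.na(r), 0, r^2)
        if (r2 >= r2_max) drop[i] <- TRUE
      }
    }
    s <- s[!drop, , drop = FALSE]
  }
  keep
}

# closed-form OLS via normal equations
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  list(beta = drop(b), se = se, df = df)
}

# Dunn z for one pair, written from the textbook formula
dunn_z_oracle <- function(groups, i, j) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  tie <- table(x)
  sigma2 <- (n * (n + 1) / 12) - sum(tie^3 - tie) / (12 * (n - 1))
  ri <- mean(r[g == i])
  rj <- mean(r[g == j])
  (ri - rj) / sqrt(sigma2 * (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
}

# plain silhouette from the definition, pairwise loops
silhouette_oracle <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  ed <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(vapply(own, function(j) ed(i, j), numeric(1)))
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(vapply(which(labels == l), function(j) ed(i, j), numeric(1)))
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Kruskal-Wallis H (tie-corrected), direct formula, for the permutation
# oracle
kw_h_oracle <- function(x, g) {
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(v) length(v) * mean(v)^2)) - 3 * (n + 1)
  tie <- table(x)
  h / (1 - sum(tie^3 - tie) / (n^3 - n))
}
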