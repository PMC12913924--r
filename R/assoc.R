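#' Genotype principal components
#'
#' Each SNP is centered at twice its allele frequency and scaled by the
#' binomial SD `sqrt(2 p (1 - p))`; missing dosages are set to 0 after
#' centering. Scores are the top-k left singular vectors scaled by their
#' singular values, so per-component sample means are 0 and components are
#' orthogonal. Constant SNPs are skipped (count reported).
#'
#' @param genotypes A [geno_matrix()] (post-QC).
#' @param k Number of components; `k = 0` returns an empty score table.
#' @return An object of class `geno_pca`: `scores` (tibble `sample`,
#'   `PC1..PCk`), plus the rotation and standardization needed to project
#'   new samples with [project_pca()].
#' @export
genotype_pca <- function(genotypes, k = 5) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  d <- genotypes$dosage
  n <- nrow(d)
  if (k >= min(dim(d)) ) abort("`k` must be < min(n samples, n SNPs).")
  if (k == 0) {
    return(structure(
      list(
        scores = tibble::tibble(sample = rownames(d)),
        rotation = NULL, center = NULL, scale = NULL, snps = character(),
        k = 0L, n_constant = 0L
      ),
      class = "geno_pca"
    ))
  }
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- which(p > 0 & p < 1)
  n_constant <- ncol(d) - length(keep)
  if (n_constant > 0)
    inform(paste0("genotype_pca: skipped ", n_constant, " constant SNP(s)."))
  if (length(keep) < k) abort("too few informative SNPs for requested `k`.")
  p <- p[keep]
  x <- sweep(d[, keep, drop = FALSE], 2, 2 * p)
  x[is.na(x)] <- 0
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  cv <- tcrossprod(x) # n x n
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values[seq_len(k)], 0)
  u <- e$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| coordinate positive
  for (j in seq_len(k)) {
    i0 <- which.max(abs(u[, j]))
    if (u[i0, j] < 0) u[, j] <- -u[, j]
  }
  scores <- u %*% diag(sqrt(vals), k, k)
  rotation <- crossprod(x, u) %*% diag(1 / pmax(sqrt(vals), 1e-12), k, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(
      scores = tibble::tibble(sample = rownames(d), !!!as.data.frame(scores)),
      rotation = rotation, center = 2 * p, scale = sqrt(2 * p * (1 - p)),
      snps = colnames(d)[keep], k = as.integer(k), n_constant = n_constant
    ),
    class = "geno_pca"
  )
}

#' Project samples onto fitted principal components
#'
#' @param pca A [genotype_pca()] fit.
#' @param genotypes A [geno_matrix()] containing the fit's SNPs.
#' @return A tibble: `sample`, `PC1..PCk`.
#' @export
project_pca <- function(pca, genotypes) {
  stopifnot(inherits(pca, "geno_pca"))
  if (pca$k == 0) return(tibble::tibble(sample = sample_ids(genotypes)))
  g <- geno_subset(genotypes, snps = pca$snps)
  x <- sweep(g$dosage, 2, pca$center)
  x[is.na(x)] <- 0
  x <- sweep(x, 2, pca$scale, "/")
  s <- x %*% pca$rotation
  colnames(s) <- paste0("PC", seq_len(pca$k))
  tibble::tibble(sample = rownames(x), !!!as.data.frame(s))
}

# Build a numeric covariate design matrix (no intercept column) from a data
# frame; factors/characters expand to treatment dummies.
.covariate_design <- function(covariates, n) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0)) {
    return(matrix(numeric(0), n, 0))
  }
  covariates <- as.data.frame(covariates)
  mm <- stats::model.matrix(~., data = covariates)
  mm[, -1, drop = FALSE]
}

.check_collinear <- function(w) {
  if (ncol(w) == 0) return(invisible())
  qr_w <- qr(w)
  if (qr_w$rank < ncol(w)) {
    dropped <- colnames(w)[qr_w$pivot[(qr_w$rank + 1):ncol(w)]]
    abort(paste0(
      "collinear covariate column(s): ", paste(dropped, collapse = ", ")
    ))
  }
}

#' Per-SNP association with a quantitative trait
#'
#' For each SNP, least squares of `phenotype ~ dosage + covariates` over
#' samples with a non-missing dosage; the reported effect, SE and p-value
#' (t distribution on the residual degrees of freedom) belong to the dosage
#' term. SNPs with too few complete cases or zero dosage variance yield NA
#' rows. A perfect fit (zero residual) is reported at the numerical floor
#' with `degenerate = TRUE`.
#'
#' @param genotypes A [geno_matrix()].
#' @param phenotype Numeric vector, one value per sample (complete).
#' @param covariates Optional data frame of covariates (rows aligned with
#'   samples); factors are expanded to indicators.
#' @return A summary-statistics tibble: `snp`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `p`, `n`, `degenerate`.
#' @export
gwas_quantitative <- function(genotypes, phenotype, covariates = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  d <- genotypes$dosage
  n <- nrow(d)
  if (length(phenotype) != n) abort("`phenotype` length must equal sample count.")
  if (anyNA(phenotype)) abort("`phenotype` must be complete.")
  wmat <- .covariate_design(covariates, n)
  .check_collinear(cbind(1, wmat))
  w <- cbind(`(Intercept)` = 1, wmat)
  p_cov <- ncol(w)
  qw <- qr(w)
  qy <- qr.resid(qw, phenotype)
  m <- ncol(d)
  beta <- se <- pv <- rep(NA_real_, m)
  nn <- integer(m)
  degen <- logical(m)
  has_na <- colSums(is.na(d)) > 0
  # fast path: complete SNPs share one residualization
  cc <- which(!has_na)
  if (length(cc)) {
    gres <- qr.resid(qw, d[, cc, drop = FALSE])
    css <- colSums(gres^2)
    ok <- css > 1e-12
    b <- colSums(gres * qy)[ok] / css[ok]
    df <- n - p_cov - 1
    rss <- pmax(sum(qy^2) - b^2 * css[ok], 0)
    sgm2 <- rss / df
    s <- sqrt(sgm2 / css[ok])
    idx <- cc[ok]
    beta[idx] <- b
    tstat <- ifelse(s > 0, b / s, Inf)
    se[idx] <- s
    pv[idx] <- 2 * pt(-abs(tstat), df)
    dg <- rss <= 1e-10 * max(sum(qy^2), 1e-300)
    pv[idx[dg]] <- .Machine$double.xmin
    degen[idx[dg]] <- TRUE
    nn[cc] <- n
  }
  for (j in which(has_na)) {
    obs <- which(!is.na(d[, j]))
    nn[j] <- length(obs)
    if (length(obs) < p_cov + 2) next
    x <- cbind(w[obs, , drop = FALSE], d[obs, j])
    if (sd(d[obs, j]) == 0) next
    fit <- stats::lm.fit(x, phenotype[obs])
    if (fit$rank < ncol(x)) next
    df <- length(obs) - ncol(x)
    rss <- sum(fit$residuals^2)
    xtx_inv <- chol2inv(chol(crossprod(x)))
    s2 <- rss / df
    beta[j] <- fit$coefficients[ncol(x)]
    se[j] <- sqrt(s2 * xtx_inv[ncol(x), ncol(x)])
    if (se[j] > 0) {
      pv[j] <- 2 * pt(-abs(beta[j] / se[j]), df)
    } else {
      pv[j] <- .Machine$double.xmin
      degen[j] <- TRUE
    }
    if (rss <= 1e-10 * sum((phenotype[obs] - mean(phenotype[obs]))^2)) {
      pv[j] <- .Machine$double.xmin
      degen[j] <- TRUE
    }
  }
  tibble::tibble(
    snp = genotypes$snps$snp, chr = genotypes$snps$chr,
    pos = genotypes$snps$pos,
    effect_allele = genotypes$snps$a1, other_allele = genotypes$snps$a2,
    beta = beta, se = se, p = pv, n = nn, degenerate = degen
  )
}

#' Per-SNP allelic case-control association
#'
#' One-degree-of-freedom allelic chi-square on the 2x2 allele-count table
#' (no covariate adjustment); the effect is reported as the log allelic odds
#' ratio with its standard error. Monomorphic SNPs yield NA rows.
#'
#' @param genotypes A [geno_matrix()].
#' @param labels Logical or 0/1 vector, one per sample (`TRUE`/1 = case).
#' @return A summary-statistics tibble as in [gwas_quantitative()].
#' @export
gwas_casecontrol <- function(genotypes, labels) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  d <- genotypes$dosage
  labels <- as.logical(labels)
  if (length(labels) != nrow(d)) abort("`labels` length must equal sample count.")
  if (!any(labels) || !any(!labels)) abort("both classes must be non-empty.")
  cs <- d[labels, , drop = FALSE]
  ct <- d[!labels, , drop = FALSE]
  a1_case <- colSums(cs, na.rm = TRUE)
  n_case <- 2 * colSums(!is.na(cs))
  a1_ctrl <- colSums(ct, na.rm = TRUE)
  n_ctrl <- 2 * colSums(!is.na(ct))
  a <- a1_case
  b <- n_case - a1_case
  cc <- a1_ctrl
  dd <- n_ctrl - a1_ctrl
  tot <- a + b + cc + dd
  stat <- tot * (a * dd - b * cc)^2 /
    ((a + b) * (cc + dd) * (a + cc) * (b + dd))
  mono <- (a + cc) == 0 | (b + dd) == 0
  stat[mono] <- NA_real_
  pv <- pchisq(stat, df = 1, lower.tail = FALSE)
  beta <- log(a * dd / (b * cc))
  sev <- sqrt(1 / a + 1 / b + 1 / cc + 1 / dd)
  beta[mono | !is.finite(beta)] <- NA_real_
  sev[is.na(beta)] <- NA_real_
  tibble::tibble(
    snp = genotypes$snps$snp, chr = genotypes$snps$chr,
    pos = genotypes$snps$pos,
    effect_allele = genotypes$snps$a1, other_allele = genotypes$snps$a2,
    beta = unname(beta), se = unname(sev), p = unname(pv),
    n = as.integer(unname(n_case + n_ctrl) / 2), degenerate = FALSE
  )
}

# r^2 between one SNP (index) and a set of SNPs, on dosages,
# pairwise-complete.
.dosage_r2 <- function(d, i, js) {
  x <- d[, i]
  r <- suppressWarnings(cor(x, d[, js, drop = FALSE], use = "pairwise.complete.obs"))
  r2 <- drop(r)^2
  r2[is.na(r2)] <- 0
  r2
}

# Greedy p-ordered selection with LD exclusion, shared by clumping and
# lead-SNP picking. Ties on p broken by position then id.
.greedy_ld_select <- function(stats, genotypes, p_max, r2_max, window_kb,
                              strict = FALSE) {
  s <- dplyr::filter(stats, !is.na(.data$p))
  s <- if (strict) dplyr::filter(s, .data$p < p_max) else dplyr::filter(s, .data$p <= p_max)
  if (nrow(s) == 0) return(character())
  s <- dplyr::arrange(s, .data$p, .data$pos, .data$snp)
  d <- genotypes$dosage
  col <- match(s$snp, colnames(d))
  if (anyNA(col)) abort("summary stats contain SNPs absent from the genotypes.")
  alive <- rep(TRUE, nrow(s))
  keep <- integer()
  for (i in seq_len(nrow(s))) {
    if (!alive[i]) next
    keep <- c(keep, i)
    near <- which(alive & seq_len(nrow(s)) > i &
      s$chr == s$chr[i] & abs(s$pos - s$pos[i]) <= window_kb * 1000)
    if (length(near)) {
      r2 <- .dosage_r2(d, col[i], col[near])
      alive[near[r2 >= r2_max]] <- FALSE
    }
  }
  s$snp[keep]
}

#' Select mutually independent lead SNPs
#'
#' Greedy: repeatedly take the smallest-p SNP with `p < p_max` not yet
#' excluded, then exclude SNPs within `window_kb` of it whose dosage r^2
#' with it is at least `r2_max`.
#'
#' @param stats Summary statistics (as from [gwas_quantitative()] or
#'   [gwas_casecontrol()]).
#' @param genotypes The matching [geno_matrix()] (for LD).
#' @param p_max Suggestive significance threshold (default 1e-5).
#' @param r2_max LD exclusion threshold (default 0.1).
#' @param window_kb Physical exclusion window (default 250 kb).
#' @return Character vector of lead SNP ids (possibly empty).
#' @export
select_lead_snps <- function(stats, genotypes, p_max = 1e-5,
                             r2_max = 0.1, window_kb = 250) {
  .greedy_ld_select(stats, genotypes, p_max, r2_max, window_kb, strict = TRUE)
}
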