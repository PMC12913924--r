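#' Polygenic score model
#'
#' A fitted per-fold scoring model: the clump-independent SNP set with
#' effect alleles and weights (the GWAS per-allele effects), the selected
#' p-value threshold, and the clumping parameters used.
#'
#' @param snps Tibble with columns `snp`, `effect_allele`, `weight`, `p`.
#' @param threshold The p-value threshold the SNP set satisfies.
#' @param r2_max,window_kb Clump parameters recorded for provenance.
#' @param fold Optional fold id.
#' @param trace Optional threshold-selection trace
#'   (tibble `threshold`, `n_snps`, `r2`).
#' @return An object of class `prs_model`.
#' @export
prs_model <- function(snps, threshold, r2_max = NA_real_,
                      window_kb = NA_real_, fold = NA_integer_,
                      trace = NULL) {
  snps <- tibble::as_tibble(snps)
  need <- c("snp", "effect_allele", "weight")
  miss <- setdiff(need, names(snps))
  if (length(miss))
    abort(paste0("`snps` is missing column(s): ", paste(miss, collapse = ", ")))
  if (!"p" %in% names(snps)) snps$p <- NA_real_
  if (any(snps$p > threshold, na.rm = TRUE))
    abort("every model SNP must satisfy p <= threshold.")
  structure(
    list(
      snps = snps, threshold = threshold, r2_max = r2_max,
      window_kb = window_kb, fold = fold, trace = trace
    ),
    class = "prs_model"
  )
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf(
    "<prs_model> %d SNPs, p-threshold %g%s\n",
    nrow(x$snps), x$threshold,
    if (!is.na(x$fold)) paste0(", fold ", x$fold) else ""
  ))
  invisible(x)
}

#' LD clumping of summary statistics
#'
#' Greedy by ascending p-value among SNPs with `p <= p_index_max`: each
#' retained index SNP removes SNPs within `window_kb` whose dosage r^2 with
#' it is at least `r2_max`. Ties on p are broken by position then id, so the
#' result is independent of input row order.
#'
#' @inheritParams select_lead_snps
#' @param p_index_max Only SNPs at or below this p enter clumping
#'   (default 1: all).
#' @return The clumped summary statistics (rows of `stats`, ascending p).
#' @export
ld_clump <- function(stats, genotypes, r2_max = 0.1, window_kb = 250,
                     p_index_max = 1.0) {
  keep <- .greedy_ld_select(stats, genotypes, p_index_max, r2_max, window_kb,
    strict = FALSE
  )
  out <- stats[match(keep, stats$snp), , drop = FALSE]
  tibble::as_tibble(out)
}

#' Score individuals with a PRS model
#'
#' Computes `PRS_j = (1/M_j) * sum_i S_i * G_ij`, the mean over the
#' individual's non-missing scored SNPs of weight times effect-allele
#' dosage; `M_j` is that non-missing count. Model SNPs absent from the
#' genotypes are dropped with a warning; when a model SNP's alleles are
#' recorded swapped in the genotypes, its dosage is reflected (`2 - G`) so
#' the score is allele-flip invariant.
#'
#' @param genotypes A [geno_matrix()].
#' @param model A [prs_model()].
#' @return A tibble: `sample`, `prs`, `m` (SNPs scored). Samples with
#'   `m = 0` get `NA` with a warning.
#' @export
score_prs <- function(genotypes, model) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(model, "prs_model"))
  snps <- model$snps
  idx <- match(snps$snp, snp_ids(genotypes))
  if (anyNA(idx)) {
    warn(paste0(
      sum(is.na(idx)), " model SNP(s) absent from genotypes; dropped."
    ))
    snps <- snps[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  if (nrow(snps) == 0) abort("no model SNPs available in the genotypes.")
  meta <- genotypes$snps[idx, ]
  d <- genotypes$dosage[, idx, drop = FALSE]
  same <- snps$effect_allele == meta$a1
  flipped <- snps$effect_allele == meta$a2
  if (any(!same & !flipped)) {
    warn(paste0(
      sum(!same & !flipped),
      " model SNP(s) with irreconcilable alleles; dropped."
    ))
    keep <- same | flipped
    snps <- snps[keep, , drop = FALSE]
    d <- d[, keep, drop = FALSE]
    flipped <- flipped[keep]
  }
  if (any(flipped)) d[, flipped] <- 2 - d[, flipped, drop = FALSE]
  m <- rowSums(!is.na(d))
  dz <- d
  dz[is.na(dz)] <- 0
  num <- drop(dz %*% snps$weight)
  prs <- unname(ifelse(m >= 1, num / m, NA_real_))
  if (any(m == 0)) {
    warn(paste0(sum(m == 0), " sample(s) with zero scored SNPs; PRS is NA."))
  }
  tibble::tibble(sample = sample_ids(genotypes), prs = prs, m = as.integer(m))
}

#' Default p-value threshold grid
#' @return Numeric vector of candidate thresholds.
#' @export
prs_threshold_grid <- function() {
  c(5e-8, 1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 1.0)
}

# incremental R^2 of `prs` over covariates for phenotype y
.incremental_r2 <- function(y, prs, wmat) {
  full <- cbind(1, wmat, prs)
  base <- cbind(1, wmat)
  r2 <- function(x) {
    fit <- stats::lm.fit(x, y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  r2(full) - r2(base)
}

#' Select the best p-value threshold for a PRS
#'
#' For each threshold in the grid, scores the target samples with the
#' clumped SNPs at or below it and fits `phenotype ~ PRS + covariates`; the
#' threshold with the largest incremental R^2 of the PRS term over the
#' covariate-only model wins. Thresholds retaining zero SNPs are skipped.
#'
#' @param stats_clumped Clumped summary statistics (from [ld_clump()]).
#' @param genotypes Target-sample [geno_matrix()].
#' @param phenotype Numeric vector for the target samples.
#' @param covariates Optional covariate data frame for the target samples.
#' @param grid Candidate thresholds (default [prs_threshold_grid()]).
#' @param fold Optional fold id stored in the result.
#' @return A [prs_model()] carrying the winning SNP set and the full
#'   `(threshold, n_snps, r2)` trace.
#' @export
optimize_threshold <- function(stats_clumped, genotypes, phenotype,
                               covariates = NULL,
                               grid = prs_threshold_grid(),
                               fold = NA_integer_) {
  if (length(grid) == 0) abort("`grid` must be non-empty.")
  if (length(phenotype) != nrow(genotypes$dosage))
    abort("`phenotype` length must equal target sample count.")
  wmat <- .covariate_design(covariates, length(phenotype))
  trace <- tibble::tibble(
    threshold = sort(grid), n_snps = NA_integer_, r2 = NA_real_
  )
  for (i in seq_len(nrow(trace))) {
    t <- trace$threshold[i]
    sel <- dplyr::filter(stats_clumped, .data$p <= t)
    trace$n_snps[i] <- nrow(sel)
    if (nrow(sel) == 0) next
    model_t <- prs_model(
      tibble::tibble(
        snp = sel$snp, effect_allele = sel$effect_allele,
        weight = sel$beta, p = sel$p
      ),
      threshold = t
    )
    sc <- score_prs(genotypes, model_t)
    if (anyNA(sc$prs)) next
    trace$r2[i] <- .incremental_r2(phenotype, sc$prs, wmat)
  }
  if (all(is.na(trace$r2)))
    abort("every threshold retained zero scorable SNPs.")
  best <- trace$threshold[which.max(trace$r2)]
  sel <- dplyr::filter(stats_clumped, .data$p <= best)
  prs_model(
    tibble::tibble(
      snp = sel$snp, effect_allele = sel$effect_allele,
      weight = sel$beta, p = sel$p
    ),
    threshold = best, fold = fold, trace = trace
  )
}
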