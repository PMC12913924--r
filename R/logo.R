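#' Random fold assignment
#'
#' Uniform random partition of samples into `k` folds whose sizes differ by
#' at most one, reproducible under the seed.
#'
#' @param sample_ids Character vector of sample ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A tibble: `sample`, `fold` (1..k).
#' @export
make_folds <- function(sample_ids, k = 5L, seed = 1L) {
  n <- length(sample_ids)
  if (k < 2) abort("`k` must be >= 2.")
  if (k > n) abort("`k` must be <= the number of samples.")
  withr::with_seed(seed, {
    fold <- sample(rep_len(seq_len(k), n))
  })
  tibble::tibble(sample = sample_ids, fold = fold)
}

# standard phenotype covariates used throughout: age, sex, smoking
# pack-year category (two indicators vs never), atopy
.cohort_covariates <- function(cohort) {
  data.frame(
    age = cohort$age,
    sex = factor(cohort$sex, levels = c("female", "male")),
    smoking = factor(cohort$smoking, levels = c("never", "0-10", ">10")),
    atopy = cohort$atopy
  )
}

#' Leave-one-group-out PRS construction
#'
#' For each fold i: a GWAS of log10 IgE is run on the four base subgroups
#' (covariates: age, sex, smoking category, atopy, and genetic principal
#' components computed on the base samples and projected onto the rest);
#' the summary statistics are LD-clumped; the p-value threshold is selected
#' on the held-out subgroup; all samples are then scored with the fold
#' model. The fold's standard error is that of the PRS coefficient in the
#' held-out covariate-adjusted regression, so the meta-analytic weights are
#' out-of-sample.
#'
#' @param genotypes Post-QC [geno_matrix()] of the reference cohort.
#' @param cohort Phenotype table with columns `sample`, `log_ige`, `age`,
#'   `sex`, `smoking`, `atopy`, aligned by id with `genotypes`.
#' @param folds A [make_folds()] assignment.
#' @param k_pcs Genetic principal components per base set (default 5).
#' @param r2_max,window_kb Clump parameters.
#' @param grid P-value threshold grid.
#' @param min_fold_size Folds smaller than this raise an error (unstable
#'   fold SEs); default 30.
#' @return An object of class `logo_fit`: `scores` (tibble `sample`,
#'   `fold`, `prs_1..prs_K`), `folds` (per-fold threshold, SNP count, SE,
#'   held-out incremental R^2), `models` (list of [prs_model()]).
#' @export
run_logo <- function(genotypes, cohort, folds, k_pcs = 5,
                     r2_max = 0.1, window_kb = 250,
                     grid = prs_threshold_grid(),
                     min_fold_size = 30) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  ids <- sample_ids(genotypes)
  if (!setequal(ids, folds$sample))
    abort("`folds` must cover exactly the genotype samples.")
  if (!all(ids %in% cohort$sample))
    abort("`cohort` must contain every genotype sample.")
  cohort <- cohort[match(ids, cohort$sample), ]
  folds <- folds[match(ids, folds$sample), ]
  k <- max(folds$fold)
  sizes <- table(factor(folds$fold, levels = seq_len(k)))
  if (any(sizes < min_fold_size))
    abort(paste0("fold(s) smaller than ", min_fold_size, " samples."))
  base_cov <- .cohort_covariates(cohort)
  prs_mat <- matrix(NA_real_, length(ids), k,
    dimnames = list(ids, paste0("prs_", seq_len(k)))
  )
  fold_tbl <- tibble::tibble(
    fold = seq_len(k), n_base = NA_integer_, n_target = NA_integer_,
    threshold = NA_real_, n_snps = NA_integer_, se = NA_real_,
    r2_holdout = NA_real_
  )
  models <- vector("list", k)
  for (i in seq_len(k)) {
    in_base <- folds$fold != i
    g_base <- geno_subset(genotypes, samples = ids[in_base])
    g_target <- geno_subset(genotypes, samples = ids[!in_base])
    y_base <- cohort$log_ige[in_base]
    y_target <- cohort$log_ige[!in_base]
    if (k_pcs > 0) {
      pca <- genotype_pca(g_base, k = k_pcs)
      pcs_all <- project_pca(pca, genotypes)
      pcs_all <- pcs_all[match(ids, pcs_all$sample), -1, drop = FALSE]
      cov_all <- cbind(base_cov, pcs_all)
    } else {
      cov_all <- base_cov
    }
    stats <- gwas_quantitative(g_base, y_base, cov_all[in_base, , drop = FALSE])
    clumped <- ld_clump(stats, g_base, r2_max = r2_max, window_kb = window_kb)
    model <- optimize_threshold(
      clumped, g_target, y_target,
      covariates = cov_all[!in_base, , drop = FALSE],
      grid = grid, fold = i
    )
    models[[i]] <- model
    sc <- score_prs(genotypes, model)
    prs_mat[, i] <- sc$prs[match(ids, sc$sample)]
    # out-of-sample SE of the PRS coefficient in the held-out subgroup
    w_t <- .covariate_design(cov_all[!in_base, , drop = FALSE], sum(!in_base))
    x <- cbind(1, w_t, prs = prs_mat[!in_base, i])
    fit <- stats::lm.fit(x, y_target)
    df <- length(y_target) - ncol(x)
    s2 <- sum(fit$residuals^2) / df
    xtx_inv <- chol2inv(chol(crossprod(x)))
    se_i <- sqrt(s2 * xtx_inv[ncol(x), ncol(x)])
    fold_tbl$n_base[i] <- sum(in_base)
    fold_tbl$n_target[i] <- sum(!in_base)
    fold_tbl$threshold[i] <- model$threshold
    fold_tbl$n_snps[i] <- nrow(model$snps)
    fold_tbl$se[i] <- se_i
    fold_tbl$r2_holdout[i] <- max(model$trace$r2, na.rm = TRUE)
  }
  scores <- tibble::tibble(
    sample = ids, fold = folds$fold,
    !!!as.data.frame(prs_mat)
  )
  structure(
    list(scores = scores, folds = fold_tbl, models = models, k = k),
    class = "logo_fit"
  )
}

#' @export
print.logo_fit <- function(x, ...) {
  cat(sprintf(
    "<logo_fit> %d folds, %d samples; thresholds: %s\n",
    x$k, nrow(x$scores), paste(signif(x$folds$threshold, 2), collapse = ", ")
  ))
  invisible(x)
}

#' Inverse-variance meta-analytic combination of fold scores
#'
#' Computes, per individual, `IgE_PRS = sum_i(PRS_i / SE_i^2) /
#' sum_i(1 / SE_i^2)` with fold-level weights, the fixed-effect
#' inverse-variance rule.
#'
#' @param fold_scores A `logo_fit`, or a data frame with a `sample` column
#'   and one `prs_*` column per fold.
#' @param fold_ses Fold standard errors (taken from the fit when
#'   `fold_scores` is a `logo_fit`). All must be finite and positive.
#' @return A tibble: `sample`, `ige_prs`.
#' @export
meta_combine <- function(fold_scores, fold_ses = NULL) {
  if (inherits(fold_scores, "logo_fit")) {
    fold_ses <- fold_ses %||% fold_scores$folds$se
    fold_scores <- fold_scores$scores
  }
  prs_cols <- grep("^prs_", names(fold_scores), value = TRUE)
  if (length(prs_cols) == 0) abort("no `prs_*` columns found.")
  if (is.null(fold_ses) || length(fold_ses) != length(prs_cols))
    abort("`fold_ses` must give one SE per fold.")
  if (any(!is.finite(fold_ses)) || any(fold_ses <= 0))
    abort("all fold SEs must be finite and positive.")
  w <- 1 / fold_ses^2
  m <- as.matrix(fold_scores[prs_cols])
  tibble::tibble(
    sample = fold_scores$sample,
    ige_prs = unname(drop(m %*% w)) / sum(w)
  )
}

#' Standardize combined scores against a reference group
#'
#' `z = (X - mu) / sigma` with `mu` and `sigma` the mean and SD of the
#' combined score among the reference samples (e.g., non-asthmatic
#' controls), so reference z-scores have mean 0 and SD 1.
#'
#' @param meta Output of [meta_combine()].
#' @param reference_ids Sample ids defining the reference distribution
#'   (default: all samples in `meta`).
#' @return A list: `scores` (tibble `sample`, `ige_prs`, `ige_prs_z`) and
#'   `reference` (list `mean`, `sd`).
#' @export
zscore_reference <- function(meta, reference_ids = meta$sample) {
  ref <- meta$ige_prs[meta$sample %in% reference_ids]
  if (length(ref) == 0) abort("reference group is empty.")
  if (anyNA(ref)) {
    warn(paste0(
      sum(is.na(ref)),
      " reference sample(s) without a combined score; excluded from mu/sigma."
    ))
    ref <- ref[!is.na(ref)]
    if (length(ref) == 0) abort("reference group is empty.")
  }
  mu <- mean(ref)
  sigma <- sd(ref)
  if (!is.finite(sigma) || sigma == 0)
    abort("degenerate reference: zero SD.")
  list(
    scores = tibble::tibble(
      sample = meta$sample, ige_prs = meta$ige_prs,
      ige_prs_z = (meta$ige_prs - mu) / sigma
    ),
    reference = list(mean = mu, sd = sigma)
  )
}

#' Apply a reference LOGO build to an external cohort
#'
#' Scores external samples with every fold model, combines the K scores
#' with the reference fold SEs (inverse-variance weights), and standardizes
#' with the reference mean and SD. A fold model with SNP coverage below 90%
#' in the external genotypes triggers a warning naming the coverage.
#'
#' @param models List of [prs_model()] from the reference build (or a
#'   `logo_fit`).
#' @param fold_ses Reference fold SEs (taken from the fit if a `logo_fit`
#'   is given).
#' @param genotypes External [geno_matrix()] (post-QC).
#' @param zref The `reference` element of [zscore_reference()].
#' @return A tibble: `sample`, `prs_1..prs_K`, `ige_prs`, `ige_prs_z`.
#' @export
apply_to_external <- function(models, fold_ses, genotypes, zref) {
  if (inherits(models, "logo_fit")) {
    fold_ses <- fold_ses %||% models$folds$se
    models <- models$models
  }
  if (length(models) == 0) abort("`models` must be non-empty.")
  if (length(fold_ses) != length(models))
    abort("`fold_ses` must give one SE per model.")
  k <- length(models)
  ids <- sample_ids(genotypes)
  m <- matrix(NA_real_, length(ids), k,
    dimnames = list(ids, paste0("prs_", seq_len(k)))
  )
  for (i in seq_len(k)) {
    cov <- mean(models[[i]]$snps$snp %in% snp_ids(genotypes))
    if (cov < 0.9) {
      warn(sprintf(
        "fold %d model: SNP coverage %.1f%% in external genotypes", i, 100 * cov
      ))
    }
    sc <- score_prs(genotypes, models[[i]])
    m[, i] <- sc$prs[match(ids, sc$sample)]
  }
  w <- 1 / fold_ses^2
  combined <- unname(drop(m %*% w)) / sum(w)
  tibble::tibble(
    sample = ids, !!!as.data.frame(m),
    ige_prs = combined,
    ige_prs_z = (combined - zref$mean) / zref$sd
  )
}
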