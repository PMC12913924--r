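#' Simulation configuration
#'
#' Bundles every tunable of the synthetic cohort generator. Defaults emulate
#' the scale of a health-checkup control cohort (n = 1,287) and a hospital
#' asthma cohort (n = 745): additive genetic effects on log10 total IgE,
#' equicorrelated LD blocks, covariate effects on realistic scales, and a
#' planted four-component case structure.
#'
#' @param n_controls,n_cases Cohort sizes.
#' @param n_snps,n_blocks SNP panel size and number of LD blocks. SNPs are
#'   assigned to blocks contiguously; blocks are mutually independent.
#' @param block_corr Latent (haplotype-level) equicorrelation within a block,
#'   in `[0, 1)`. The threshold step attenuates this somewhat on the dosage
#'   scale.
#' @param maf_range Minor-allele-frequency range, both ends in `(0, 0.5]`.
#' @param n_causal Number of causal SNPs (at most one per block when
#'   `n_causal <= n_blocks`).
#' @param h2 Fraction of (non-covariate) phenotypic variance that is genetic,
#'   in `[0, 1)`.
#' @param sigma_p Phenotypic SD of log10 IgE excluding covariate effects
#'   (default 0.58, a typical adult value).
#' @param intercept Mean log10 IgE (default 1.78).
#' @param covariate_effects Named numeric vector of additive effects on log10
#'   IgE for `age` (per year), `sex_male`, `smoking_0_10`, `smoking_gt10`
#'   (pack-year categories vs never), and `atopy`.
#' @param cluster_spec Data frame describing the planted case components; see
#'   [asthma_cluster_spec()].
#' @param missing_rate Marginal probability that a genotype call is missing.
#' @param seed Integer seed; every generator is bit-reproducible under it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_controls = 1287L,
                       n_cases = 745L,
                       n_snps = 10000L,
                       n_blocks = 500L,
                       block_corr = 0.7,
                       maf_range = c(0.05, 0.5),
                       n_causal = 50L,
                       h2 = 0.25,
                       sigma_p = 0.58,
                       intercept = 1.78,
                       covariate_effects = c(
                         age = 0.002, sex_male = 0.12,
                         smoking_0_10 = 0.05, smoking_gt10 = 0.12,
                         atopy = 0.35
                       ),
                       cluster_spec = asthma_cluster_spec(),
                       missing_rate = 0.002,
                       seed = 1L) {
  chk_count <- function(x, nm, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
      abort(paste0("`", nm, "` must be a single integer >= ", min, "."))
  }
  chk_count(n_controls, "n_controls")
  chk_count(n_cases, "n_cases", min = 0)
  chk_count(n_snps, "n_snps")
  chk_count(n_blocks, "n_blocks")
  chk_count(n_causal, "n_causal", min = 0)
  if (n_causal > n_snps) abort("`n_causal` must be <= `n_snps`.")
  if (n_blocks > n_snps) abort("`n_blocks` must be <= `n_snps`.")
  if (!is.numeric(block_corr) || block_corr < 0 || block_corr >= 1)
    abort("`block_corr` must be in [0, 1).")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
    maf_range[1] > maf_range[2])
    abort("`maf_range` must be an increasing pair within (0, 0.5].")
  if (!is.numeric(h2) || h2 < 0 || h2 >= 1) abort("`h2` must be in [0, 1).")
  if (missing_rate < 0 || missing_rate >= 1)
    abort("`missing_rate` must be in [0, 1).")
  cluster_spec <- tibble::as_tibble(cluster_spec)
  if (abs(sum(cluster_spec$prop) - 1) > 1e-8)
    abort("`cluster_spec` mixing proportions must sum to 1.")
  sd_cols <- grep("_sd$", names(cluster_spec), value = TRUE)
  if (any(as.matrix(cluster_spec[sd_cols]) <= 0))
    abort("`cluster_spec` component SDs must all be positive.")
  structure(
    list(
      n_controls = as.integer(n_controls), n_cases = as.integer(n_cases),
      n_snps = as.integer(n_snps), n_blocks = as.integer(n_blocks),
      block_corr = block_corr, maf_range = maf_range,
      n_causal = as.integer(n_causal), h2 = h2,
      sigma_p = sigma_p, intercept = intercept,
      covariate_effects = covariate_effects,
      cluster_spec = cluster_spec,
      missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Planted asthma cluster components
#'
#' The default component means/SDs for (genetic burden z, log10 IgE, onset
#' age, percent-predicted FEV1) follow the published characteristics of four
#' adult asthma clusters: one adult-onset cluster with markedly high genetic
#' IgE burden, one childhood-onset highly atopic cluster, one smoking-related
#' obstructed cluster, and one late-onset low-IgE cluster. Mixing proportions
#' follow the reported cluster sizes (199/157/178/173).
#'
#' @param prs_z_mean,prs_z_sd Genetic-burden component means/SDs (z scale).
#' @param log_ige_mean,log_ige_sd log10 IgE component means/SDs.
#' @param onset_mean,onset_sd Asthma onset age means/SDs (years).
#' @param pfev1_mean,pfev1_sd Percent-predicted FEV1 means/SDs.
#' @param prop Mixing proportions (must sum to 1).
#' @return A tibble with one row per component.
#' @export
asthma_cluster_spec <- function(prs_z_mean = c(1.0, 0.3, -0.4, -0.7),
                                prs_z_sd = c(0.40, 0.40, 0.40, 0.40),
                                log_ige_mean = c(2.11, 2.48, 2.47, 1.83),
                                log_ige_sd = c(0.54, 0.52, 0.60, 0.61),
                                onset_mean = c(48.9, 9.9, 49.2, 54.8),
                                onset_sd = c(15, 7, 14, 14),
                                pfev1_mean = c(87.1, 79.7, 64.7, 103.8),
                                pfev1_sd = c(19.9, 20.7, 17.0, 17.1),
                                prop = c(199, 157, 178, 173) / 707) {
  tibble::tibble(
    component = seq_along(prop), prop = prop,
    prs_z_mean = prs_z_mean, prs_z_sd = prs_z_sd,
    log_ige_mean = log_ige_mean, log_ige_sd = log_ige_sd,
    onset_mean = onset_mean, onset_sd = onset_sd,
    pfev1_mean = pfev1_mean, pfev1_sd = pfev1_sd
  )
}

# SNP panel metadata: maf, block, chromosome, position. Blocks are laid out
# along chromosomes 1..22 with 5 kb spacing inside a block and 1 Mb between
# block starts, so a 250 kb clumping window rarely spans two blocks.
.sim_panel <- function(config) {
  m <- config$n_snps
  block <- rep(seq_len(config$n_blocks), length.out = m)
  block <- sort(block)
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  chr <- ((block - 1L) %% 22L) + 1L
  block_on_chr <- (block - 1L) %/% 22L
  within <- stats::ave(seq_len(m), block, FUN = seq_along)
  pos <- block_on_chr * 1e6 + within * 5000L
  tibble::tibble(
    snp = sprintf("rs%06d", seq_len(m)),
    chr = as.character(chr), pos = as.integer(pos),
    a1 = "A", a2 = "G",
    maf = maf, block = block
  )
}

# Draw genotypes for `ids` from a panel: latent Gaussian equicorrelation
# within blocks, thresholded per haplotype, summed to dosage. HWE holds per
# SNP because the two haplotypes are independent.
.sim_geno_from_panel <- function(panel, block_corr, ids) {
  n <- length(ids)
  m <- nrow(panel)
  thr <- qnorm(panel$maf)
  dosage <- matrix(0, n, m, dimnames = list(ids, panel$snp))
  rho <- block_corr
  for (hap in 1:2) {
    blocks <- split(seq_len(m), panel$block)
    f <- matrix(rnorm(n * length(blocks)), n, length(blocks))
    alle <- matrix(0L, n, m)
    for (bi in seq_along(blocks)) {
      idx <- blocks[[bi]]
      e <- matrix(rnorm(n * length(idx)), n, length(idx))
      z <- sqrt(rho) * f[, bi] + sqrt(1 - rho) * e
      alle[, idx] <- (z < rep(thr[idx], each = n)) * 1L
    }
    dosage <- dosage + alle
  }
  dosage
}

#' Simulate a genotype reference panel
#'
#' Generates a control-cohort genotype matrix with block LD structure and a
#' ground-truth model (causal SNPs and their effects) for parameter-recovery
#' testing. Missing calls are injected completely at random at
#' `config$missing_rate` after genotypes are drawn.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` (a [geno_matrix()]) and `truth`
#'   (class `true_model`: the panel, causal SNP table, covariate effects and
#'   noise SD).
#' @export
simulate_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    panel <- .sim_panel(config)
    ids <- sprintf("C%05d", seq_len(config$n_controls))
    dosage <- .sim_geno_from_panel(panel, config$block_corr, ids)
    # causal SNPs: at most one per block so per-SNP variances add
    causal <- tibble::tibble(snp = character(), effect = numeric())
    if (config$n_causal > 0) {
      if (config$n_causal <= config$n_blocks) {
        blocks <- sample(unique(panel$block), config$n_causal)
        snp_idx <- vapply(
          blocks,
          function(b) sample(which(panel$block == b), 1L), integer(1)
        )
      } else {
        snp_idx <- sample(nrow(panel), config$n_causal)
      }
      raw <- rnorm(config$n_causal)
      p <- panel$maf[snp_idx]
      v_raw <- sum(raw^2 * 2 * p * (1 - p))
      target <- config$h2 * config$sigma_p^2
      scale <- if (v_raw > 0 && target > 0) sqrt(target / v_raw) else 0
      causal <- tibble::tibble(snp = panel$snp[snp_idx], effect = raw * scale)
    }
    if (config$missing_rate > 0) {
      miss <- runif(length(dosage)) < config$missing_rate
      dosage[miss] <- NA_real_
    }
    truth <- structure(
      list(
        panel = panel, causal = causal,
        covariate_effects = config$covariate_effects,
        noise_sd = sqrt(1 - config$h2) * config$sigma_p,
        h2 = config$h2, sigma_p = config$sigma_p,
        intercept = config$intercept, block_corr = config$block_corr
      ),
      class = "true_model"
    )
    list(
      genotypes = geno_matrix(dosage, panel[c("snp", "chr", "pos", "a1", "a2")]),
      truth = truth
    )
  })
}

#' @export
print.true_model <- function(x, ...) {
  cat(sprintf(
    "<true_model> %d SNPs, %d causal, h2 = %.2f\n",
    nrow(x$panel), nrow(x$causal), x$h2
  ))
  invisible(x)
}

# additive genetic value from causal SNPs; missing dosages imputed at 2*maf
.genetic_value <- function(genotypes, truth) {
  if (nrow(truth$causal) == 0) {
    return(setNames(rep(0, nrow(genotypes$dosage)), sample_ids(genotypes)))
  }
  idx <- match(truth$causal$snp, snp_ids(genotypes))
  if (anyNA(idx)) abort("causal SNPs missing from the genotype panel.")
  d <- genotypes$dosage[, idx, drop = FALSE]
  maf <- truth$panel$maf[match(truth$causal$snp, truth$panel$snp)]
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- 2 * maf[j]
  drop(d %*% truth$causal$effect)
}

#' Simulate phenotypes and covariates for a cohort
#'
#' log10 total IgE is built as intercept + centered genetic value + covariate
#' terms + Gaussian noise, with the noise SD chosen so the genetic variance
#' fraction (excluding covariates) matches the configured heritability.
#' Covariate marginals emulate an adult Japanese health-checkup cohort
#' (51.4% female, mean age 51.3, 55.8% never-smokers, 57.8% atopic).
#'
#' @param genotypes A [geno_matrix()] whose samples to phenotype.
#' @param truth The `true_model` from [simulate_reference_panel()].
#' @param config The same [sim_config()].
#' @param seed Optional seed override (defaults to `config$seed + 1`).
#' @return A tibble with columns `sample`, `log_ige`, `age`, `sex`,
#'   `smoking`, `atopy`, `pfev1`, `asthma`, `onset_age`, and the ground-truth
#'   column `genetic_value`.
#' @export
simulate_phenotypes <- function(genotypes, truth, config,
                                seed = config$seed + 1L) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(truth, "true_model"))
  ids <- sample_ids(genotypes)
  withr::with_seed(seed, {
    n <- length(ids)
    gv <- .genetic_value(genotypes, truth)
    age <- pmin(pmax(round(rnorm(n, 51.3, 10)), 30), 84)
    sex <- ifelse(runif(n) < 0.514, "female", "male")
    smoking <- sample(c("never", "0-10", ">10"), n,
      replace = TRUE, prob = c(0.558, 0.130, 0.312)
    )
    atopy <- as.integer(runif(n) < 0.578)
    pfev1 <- rnorm(n, 92.4, 12.5)
    ce <- truth$covariate_effects
    cov_term <- ce[["age"]] * (age - 51.3) +
      ce[["sex_male"]] * (sex == "male") +
      ce[["smoking_0_10"]] * (smoking == "0-10") +
      ce[["smoking_gt10"]] * (smoking == ">10") +
      ce[["atopy"]] * atopy
    log_ige <- truth$intercept + (gv - mean(gv)) + cov_term +
      rnorm(n, 0, truth$noise_sd)
    tibble::tibble(
      sample = ids, log_ige = log_ige, age = age, sex = sex,
      smoking = smoking, atopy = atopy, pfev1 = pfev1,
      asthma = FALSE, onset_age = NA_real_, genetic_value = gv
    )
  })
}

#' Draw planted cluster features directly
#'
#' Samples the four clustering features (genetic burden z, log10 IgE, onset
#' age, percent-predicted FEV1) from the mixture components of a cluster
#' specification, without any genotype layer. Used to exercise the clustering
#' and centroid modules against a known partition.
#'
#' @param spec A component table as from [asthma_cluster_spec()].
#' @param n Number of cases.
#' @param seed Integer seed.
#' @return A tibble: `sample`, `cluster_truth`, `prs_z`, `log_ige`,
#'   `onset_age`, `pfev1`.
#' @export
simulate_cluster_features <- function(spec = asthma_cluster_spec(), n = 707L,
                                      seed = 1L) {
  spec <- tibble::as_tibble(spec)
  if (any(as.matrix(spec[grep("_sd$", names(spec))]) <= 0))
    abort("component SDs must be positive.")
  withr::with_seed(seed, {
    comp <- sample(nrow(spec), n, replace = TRUE, prob = spec$prop)
    s <- spec[comp, ]
    tibble::tibble(
      sample = sprintf("A%05d", seq_len(n)),
      cluster_truth = comp,
      prs_z = rnorm(n, s$prs_z_mean, s$prs_z_sd),
      log_ige = rnorm(n, s$log_ige_mean, s$log_ige_sd),
      onset_age = pmax(rnorm(n, s$onset_mean, s$onset_sd), 0),
      pfev1 = rnorm(n, s$pfev1_mean, s$pfev1_sd)
    )
  })
}

#' Simulate an asthma case cohort with planted cluster structure
#'
#' Cases share the control panel's SNPs, allele frequencies and LD structure.
#' Each case is assigned a mixture component; its genetic burden is planted
#' by redrawing the causal LD blocks from a small candidate pool and keeping
#' the draw whose standardized genetic value is closest to the component
#' target, so the burden gradient is visible to genotype-based scores.
#' Onset age, log IgE and pFEV1 are drawn from the component distributions.
#'
#' @param config A [sim_config()].
#' @param truth The `true_model` of the matching reference panel.
#' @param pool Candidate draws per case for burden planting (default 16).
#' @param burden_gain Multiplier applied to the component burden targets on
#'   the true-burden scale (default 2). A genotype-derived score is an
#'   attenuated correlate of true burden (correlation about 0.5 under the
#'   default generator settings), so planting at twice the target makes the
#'   planted components appear on the measured-score scale at roughly the
#'   separations the component spec states.
#' @return A list: `genotypes` (cases only) and `cohort` (tibble with
#'   phenotype, covariates, `cluster_truth`).
#' @export
simulate_asthma_cohort <- function(config, truth, pool = 16L,
                                   burden_gain = 2) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "true_model"))
  spec <- config$cluster_spec
  if (any(as.matrix(spec[grep("_sd$", names(spec))]) <= 0))
    abort("cluster_spec component SDs must be positive.")
  withr::with_seed(config$seed + 2L, {
    n <- config$n_cases
    ids <- sprintf("A%05d", seq_len(n))
    panel <- truth$panel
    dosage <- .sim_geno_from_panel(panel, truth$block_corr, ids)
    comp <- sample(nrow(spec), n, replace = TRUE, prob = spec$prop)
    s <- spec[comp, ]
    gv_sd <- sqrt(truth$h2) * truth$sigma_p
    if (nrow(truth$causal) > 0 && gv_sd > 0) {
      target_z <- burden_gain * rnorm(n, s$prs_z_mean, s$prs_z_sd)
      cidx <- match(truth$causal$snp, panel$snp)
      cblocks <- unique(panel$block[cidx])
      bidx <- which(panel$block %in% cblocks)
      sub_panel <- panel[bidx, ]
      eff <- numeric(length(bidx))
      eff[match(truth$causal$snp, sub_panel$snp)] <- truth$causal$effect
      best <- dosage[, bidx, drop = FALSE]
      best_gv <- drop(best %*% eff)
      mu_gv <- sum(truth$causal$effect * 2 *
        panel$maf[cidx])
      best_err <- abs((best_gv - mu_gv) / gv_sd - target_z)
      for (p in seq_len(pool - 1L)) {
        cand <- .sim_geno_from_panel(sub_panel, truth$block_corr, ids)
        gvc <- drop(cand %*% eff)
        err <- abs((gvc - mu_gv) / gv_sd - target_z)
        take <- err < best_err
        if (any(take)) {
          best[take, ] <- cand[take, ]
          best_gv[take] <- gvc[take]
          best_err[take] <- err[take]
        }
      }
      dosage[, bidx] <- best
    }
    if (config$missing_rate > 0) {
      miss <- runif(length(dosage)) < config$missing_rate
      dosage[miss] <- NA_real_
    }
    geno <- geno_matrix(dosage, panel[c("snp", "chr", "pos", "a1", "a2")])
    age <- pmin(pmax(round(rnorm(n, 58.3, 12)), 19), 90)
    sex <- ifelse(runif(n) < 0.573, "female", "male")
    smoking <- sample(c("never", "0-10", ">10"), n,
      replace = TRUE, prob = c(0.605, 0.145, 0.250)
    )
    atopy <- as.integer(runif(n) < 0.704)
    cohort <- tibble::tibble(
      sample = ids,
      log_ige = rnorm(n, s$log_ige_mean, s$log_ige_sd),
      age = age, sex = sex, smoking = smoking, atopy = atopy,
      pfev1 = rnorm(n, s$pfev1_mean, s$pfev1_sd),
      asthma = TRUE,
      onset_age = pmax(rnorm(n, s$onset_mean, s$onset_sd), 0),
      cluster_truth = comp
    )
    list(genotypes = geno, cohort = cohort)
  })
}

#' Inject quality-control artifacts into a genotype matrix
#'
#' Adds the failure modes the QC module is meant to catch: targeted
#' per-sample missingness, duplicated samples, Mendelian-consistent
#' parent-offspring pairs, and heterozygosity-inflated samples. An empty
#' spec returns the input unchanged.
#'
#' @param genotypes A [geno_matrix()].
#' @param spec A list with any of:
#'   * `missing`: list(`ids`, `rate`) raise those samples' missingness to
#'     about `rate` (default 0.15);
#'   * `duplicates`: named character vector, `new_id = source_id`;
#'   * `offspring`: named character vector, `child_id = parent_id` (the
#'     untransmitted allele is drawn from the sample allele frequency);
#'   * `het_outliers`: list(`ids`, `fraction`) convert that fraction of
#'     homozygous calls to heterozygous.
#' @param seed Integer seed.
#' @return A `geno_matrix` (possibly with appended samples).
#' @export
inject_artifacts <- function(genotypes, spec = list(), seed = 1L) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (length(spec) == 0) return(genotypes)
  unknown <- setdiff(names(spec), c("missing", "duplicates", "offspring", "het_outliers"))
  if (length(unknown))
    abort(paste0("unknown artifact spec element(s): ", paste(unknown, collapse = ", ")))
  d <- genotypes$dosage
  withr::with_seed(seed, {
    if (!is.null(spec$missing)) {
      ids <- spec$missing$ids
      rate <- spec$missing$rate %||% 0.15
      bad <- setdiff(ids, rownames(d))
      if (length(bad)) abort(paste0("unknown sample id(s): ", paste(bad, collapse = ", ")))
      for (id in ids) {
        row <- d[id, ]
        n_target <- ceiling(rate * length(row))
        n_add <- n_target - sum(is.na(row))
        if (n_add > 0) {
          pick <- sample(which(!is.na(row)), n_add)
          d[id, pick] <- NA_real_
        }
      }
    }
    freq <- colMeans(d, na.rm = TRUE) / 2
    if (!is.null(spec$duplicates)) {
      src <- unname(spec$duplicates)
      bad <- setdiff(src, rownames(d))
      if (length(bad)) abort(paste0("unknown sample id(s): ", paste(bad, collapse = ", ")))
      dup <- d[src, , drop = FALSE]
      rownames(dup) <- names(spec$duplicates)
      d <- rbind(d, dup)
    }
    if (!is.null(spec$offspring)) {
      src <- unname(spec$offspring)
      bad <- setdiff(src, rownames(d))
      if (length(bad)) abort(paste0("unknown sample id(s): ", paste(bad, collapse = ", ")))
      kids <- matrix(NA_real_, length(src), ncol(d),
        dimnames = list(names(spec$offspring), colnames(d))
      )
      for (i in seq_along(src)) {
        g <- d[src[i], ]
        transmitted <- ifelse(g == 2, 1L, ifelse(g == 0, 0L, rbinom(length(g), 1, 0.5)))
        other <- rbinom(length(g), 1, freq)
        kid <- transmitted + other
        kid[is.na(g)] <- rbinom(sum(is.na(g)), 2, freq[is.na(g)])
        kids[i, ] <- kid
      }
      d <- rbind(d, kids)
    }
    if (!is.null(spec$het_outliers)) {
      ids <- spec$het_outliers$ids
      frac <- spec$het_outliers$fraction %||% 0.5
      bad <- setdiff(ids, rownames(d))
      if (length(bad)) abort(paste0("unknown sample id(s): ", paste(bad, collapse = ", ")))
      for (id in ids) {
        hom <- which(!is.na(d[id, ]) & d[id, ] != 1)
        flip <- sample(hom, floor(frac * length(hom)))
        d[id, flip] <- 1
      }
    }
  })
  geno_matrix(d, genotypes$snps)
}
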