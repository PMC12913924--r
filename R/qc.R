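#' Quality-control thresholds
#'
#' Defaults follow standard GWAS practice: samples are dropped for > 10%
#' missing genotypes, heterozygosity beyond 3 SD of the cohort mean, or
#' kinship above the second-degree bound (KING-robust 0.0884); SNPs are
#' dropped for call rate < 0.99, minor allele frequency < 0.01, or exact
#' Hardy-Weinberg p < 1e-6.
#'
#' @param sample_missing_max Maximum per-sample missing fraction.
#' @param het_sd_bound Heterozygosity outlier bound, in SD units.
#' @param kinship_threshold KING-robust kinship above which a pair is
#'   flagged as related (0.0884 = second-degree lower bound).
#' @param snp_call_rate_min Minimum per-SNP call rate.
#' @param maf_min Minimum minor allele frequency.
#' @param hwe_p_min Minimum exact Hardy-Weinberg p-value.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(sample_missing_max = 0.10,
                      het_sd_bound = 3,
                      kinship_threshold = 0.0884,
                      snp_call_rate_min = 0.99,
                      maf_min = 0.01,
                      hwe_p_min = 1e-6) {
  for (nm in c("sample_missing_max", "kinship_threshold", "snp_call_rate_min",
               "maf_min", "hwe_p_min")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1)
      abort(paste0("`", nm, "` must be a single value in (0, 1)."))
  }
  if (het_sd_bound <= 0) abort("`het_sd_bound` must be > 0.")
  structure(
    list(
      sample_missing_max = sample_missing_max, het_sd_bound = het_sd_bound,
      kinship_threshold = kinship_threshold,
      snp_call_rate_min = snp_call_rate_min, maf_min = maf_min,
      hwe_p_min = hwe_p_min
    ),
    class = "qc_config"
  )
}

#' Sample-level quality control
#'
#' Flags samples by missingness (> `sample_missing_max`), then flags
#' heterozygosity outliers: het rate = heterozygous calls / non-missing
#' calls, with mean and SD computed once over the samples that passed the
#' missingness filter (no iteration). Each excluded sample carries exactly
#' one primary reason.
#'
#' @param genotypes A [geno_matrix()].
#' @param config A [qc_config()].
#' @return A tibble: `sample`, `missing_rate`, `het_rate`, `excluded`,
#'   `reason` (`"missingness"`, `"heterozygosity"`, or `NA`).
#' @export
sample_qc <- function(genotypes, config = qc_config()) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  d <- genotypes$dosage
  if (nrow(d) < 2) abort("sample QC needs at least 2 samples.")
  miss <- rowMeans(is.na(d))
  het <- rowSums(d == 1, na.rm = TRUE) / rowSums(!is.na(d))
  flag_miss <- miss > config$sample_missing_max
  ok <- !flag_miss
  mu <- mean(het[ok])
  s <- sd(het[ok])
  flag_het <- ok & is.finite(s) & s > 0 &
    abs(het - mu) > config$het_sd_bound * s
  out <- tibble::tibble(
    sample = rownames(d),
    missing_rate = unname(miss),
    het_rate = unname(het),
    excluded = flag_miss | flag_het,
    reason = dplyr::case_when(
      flag_miss ~ "missingness",
      flag_het ~ "heterozygosity",
      TRUE ~ NA_character_
    )
  )
  if (all(out$excluded))
    abort("sample QC excluded every sample; check thresholds or input.")
  out
}

#' KING-robust pairwise kinship
#'
#' For each sample pair, the within-pair robust estimator
#' `phi = (N_both_het - 2 * N_opposite_hom) / (N_het_i + N_het_j)` over SNPs
#' non-missing in both samples. Expected values: 0.5 for duplicates, 0.25
#' for parent-offspring, ~0 for unrelated pairs. Pairs with no heterozygous
#' calls in either member get `NA`.
#'
#' @param genotypes A [geno_matrix()].
#' @param min_kinship Only return pairs with kinship above this value (or
#'   `NA` kinship); default `-Inf` returns all pairs.
#' @return A tibble: `sample1`, `sample2`, `kinship`.
#' @export
kinship_matrix <- function(genotypes, min_kinship = -Inf) {
  d <- genotypes$dosage
  n <- nrow(d)
  if (n < 2) abort("kinship needs at least 2 samples.")
  M <- !is.na(d)
  H <- (d == 1) & M
  A <- (d == 0) & M
  B <- (d == 2) & M
  storage.mode(H) <- "double"
  storage.mode(A) <- "double"
  storage.mode(B) <- "double"
  storage.mode(M) <- "double"
  n_both_het <- tcrossprod(H)
  n_opp <- tcrossprod(A, B)
  n_opp <- n_opp + t(n_opp)
  het_i <- tcrossprod(H, M) # het in i among non-missing in j
  denom <- het_i + t(het_i)
  phi <- (n_both_het - 2 * n_opp) / denom
  phi[denom == 0] <- NA_real_
  ut <- which(upper.tri(phi), arr.ind = TRUE)
  out <- tibble::tibble(
    sample1 = rownames(d)[ut[, 1]],
    sample2 = rownames(d)[ut[, 2]],
    kinship = phi[ut]
  )
  dplyr::filter(out, is.na(.data$kinship) | .data$kinship > min_kinship)
}

#' Choose samples to drop from related pairs
#'
#' Flags pairs above the kinship threshold and marks one member of each for
#' removal: the member with higher missingness, ties broken by removing the
#' later sample (by input order).
#'
#' @param kinship Output of [kinship_matrix()].
#' @param genotypes The matching [geno_matrix()] (for missing rates and
#'   sample order).
#' @param threshold Kinship above which a pair counts as related.
#' @return A tibble: `sample`, `reason = "relatedness"` (possibly empty).
#' @export
kinship_filter <- function(kinship, genotypes,
                           threshold = qc_config()$kinship_threshold) {
  flagged <- dplyr::filter(kinship, !is.na(.data$kinship), .data$kinship > threshold)
  if (nrow(flagged) == 0) {
    return(tibble::tibble(sample = character(), reason = character()))
  }
  miss <- rowMeans(is.na(genotypes$dosage))
  ord <- setNames(seq_along(sample_ids(genotypes)), sample_ids(genotypes))
  drop <- character()
  for (i in seq_len(nrow(flagged))) {
    s1 <- flagged$sample1[i]
    s2 <- flagged$sample2[i]
    if (s1 %in% drop || s2 %in% drop) next
    pick <- if (miss[s1] > miss[s2]) {
      s1
    } else if (miss[s2] > miss[s1]) {
      s2
    } else if (ord[s1] > ord[s2]) s1 else s2
    drop <- c(drop, pick)
  }
  tibble::tibble(sample = drop, reason = "relatedness")
}

#' SNP-level quality control
#'
#' Excludes SNPs with call rate below `snp_call_rate_min`, minor allele
#' frequency (from non-missing calls) below `maf_min`, or exact
#' Hardy-Weinberg p below `hwe_p_min`. Reasons are assigned with priority
#' call rate > MAF > HWE so each exclusion has one primary reason.
#'
#' @inheritParams sample_qc
#' @return A tibble: `snp`, `call_rate`, `maf`, `hwe_p`, `excluded`,
#'   `reason`.
#' @export
snp_qc <- function(genotypes, config = qc_config()) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  d <- genotypes$dosage
  if (nrow(d) < 2) abort("SNP QC needs at least 2 samples.")
  call_rate <- colMeans(!is.na(d))
  n_aa <- colSums(d == 0, na.rm = TRUE)
  n_ab <- colSums(d == 1, na.rm = TRUE)
  n_bb <- colSums(d == 2, na.rm = TRUE)
  freq <- (2 * n_bb + n_ab) / (2 * (n_aa + n_ab + n_bb))
  maf <- pmin(freq, 1 - freq)
  hwe_p <- hwe_exact_test(n_aa, n_ab, n_bb)
  fail_cr <- call_rate < config$snp_call_rate_min
  fail_maf <- !fail_cr & maf < config$maf_min
  fail_hwe <- !fail_cr & !fail_maf & hwe_p < config$hwe_p_min
  out <- tibble::tibble(
    snp = colnames(d),
    call_rate = unname(call_rate), maf = unname(maf),
    hwe_p = unname(hwe_p),
    excluded = fail_cr | fail_maf | fail_hwe,
    reason = dplyr::case_when(
      fail_cr ~ "call_rate",
      fail_maf ~ "maf",
      fail_hwe ~ "hwe",
      TRUE ~ NA_character_
    )
  )
  if (all(out$excluded)) warn("SNP QC excluded every SNP.")
  out
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the total probability of all heterozygote counts (same parity as the
#' minor allele count) whose conditional probability does not exceed that of
#' the observed count. Monomorphic SNPs return p = 1. Vectorized over
#' genotype count triples.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (vectors of equal length).
#' @return Numeric vector of p-values in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0, na.rm = TRUE))
    abort("genotype counts must be non-negative.")
  mapply(.hwe_exact_one, n_aa, n_ab, n_bb)
}

.hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (is.na(n) || n < 1) return(NA_real_)
  n1 <- 2 * min(n_aa, n_bb) + n_ab # minor allele count
  if (n1 == 0) return(1)
  h <- seq(n1 %% 2, n1, by = 2) # attainable heterozygote counts
  # log conditional probability up to a constant:
  # Pr(h) proportional to 2^h * n! / (h! * ((n1-h)/2)! * ((2n-n1-h)/2)!)
  lp <- h * log(2) - lfactorial(h) - lfactorial((n1 - h) / 2) -
    lfactorial((2 * n - n1 - h) / 2)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  p_obs <- p[match(n_ab, h)]
  sum(p[p <= p_obs * (1 + 1e-10)])
}

#' Run full sample-then-SNP quality control
#'
#' Applies [sample_qc()], [kinship_matrix()]/[kinship_filter()], then
#' [snp_qc()] on the remaining samples, in that order, and returns the
#' filtered matrix plus a combined exclusion report.
#'
#' @inheritParams sample_qc
#' @param kinship_snps Maximum number of SNPs used for the kinship scan
#'   (evenly thinned); `Inf` uses all.
#' @return A list: `genotypes` (filtered [geno_matrix()]), `samples`
#'   (sample report incl. relatedness), `snps` (SNP report).
#' @export
run_qc <- function(genotypes, config = qc_config(), kinship_snps = 5000) {
  samp <- sample_qc(genotypes, config)
  keep <- samp$sample[!samp$excluded]
  g1 <- geno_subset(genotypes, samples = keep)
  thin <- snp_ids(g1)
  if (length(thin) > kinship_snps) {
    thin <- thin[round(seq(1, length(thin), length.out = kinship_snps))]
  }
  kin <- kinship_matrix(geno_subset(g1, snps = thin),
    min_kinship = config$kinship_threshold
  )
  rel <- kinship_filter(kin, g1, threshold = config$kinship_threshold)
  keep2 <- setdiff(keep, rel$sample)
  g2 <- geno_subset(g1, samples = keep2)
  snps <- snp_qc(g2, config)
  g3 <- geno_subset(g2, snps = snps$snp[!snps$excluded])
  samples <- dplyr::rows_update(
    samp,
    tibble::tibble(sample = rel$sample, excluded = TRUE, reason = "relatedness"),
    by = "sample"
  )
  list(genotypes = g3, samples = samples, snps = snps)
}
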