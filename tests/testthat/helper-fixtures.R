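# Small genotype fixtures built in code.

# wrap a plain dosage matrix as a geno_matrix with simple metadata
as_geno <- function(d, chr = 1L, pos = NULL, a1 = "A", a2 = "G") {
  if (is.null(rownames(d))) rownames(d) <- sprintf("S%03d", seq_len(nrow(d)))
  if (is.null(colnames(d))) colnames(d) <- sprintf("rs%04d", seq_len(ncol(d)))
  if (is.null(pos)) pos <- seq_len(ncol(d)) * 1000L
  geno_matrix(d, tibble::tibble(
    snp = colnames(d), chr = as.character(rep_len(chr, ncol(d))),
    pos = as.integer(pos),
    a1 = rep_len(a1, ncol(d)), a2 = rep_len(a2, ncol(d))
  ))
}

# independent binomial genotypes (no LD), HWE by construction
binom_geno <- function(n, m, maf = 0.3, seed = 1) {
  withr::with_seed(seed, {
    d <- vapply(rep_len(maf, m), function(p) rbinom(n, 2, p), numeric(n))
  })
  as_geno(matrix(d, n, m))
}

# well-separated 4-component feature table (planted partition)
separated_features <- function(n = 800, sep = 6, seed = 1) {
  spec <- asthma_cluster_spec(
    prs_z_mean = c(sep, 0, 0, 0), prs_z_sd = rep(1, 4),
    log_ige_mean = c(0, sep, 0, 0), log_ige_sd = rep(1, 4),
    onset_mean = c(50, 50, 50 + sep, 50), onset_sd = rep(1, 4),
    pfev1_mean = c(0, 0, 0, sep), pfev1_sd = rep(1, 4),
    prop = rep(0.25, 4)
  )
  simulate_cluster_features(spec, n = n, seed = seed)
}

# small simulated cohort ready for LOGO runs
small_logo_cohort <- function(n = 400, n_snps = 800, h2 = 0.3, n_causal = 20,
                              seed = 1, missing_rate = 0.002) {
  cfg <- sim_config(
    n_controls = n, n_cases = 0, n_snps = n_snps,
    n_blocks = max(1L, n_snps %/% 20L), h2 = h2, n_causal = n_causal,
    seed = seed, missing_rate = missing_rate
  )
  ref <- simulate_reference_panel(cfg)
  list(
    config = cfg, genotypes = ref$genotypes, truth = ref$truth,
    cohort = simulate_phenotypes(ref$genotypes, ref$truth, cfg)
  )
}
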