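test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(n_causal = 50, n_snps = 20), "n_causal")
  expect_error(sim_config(block_corr = 1), "block_corr")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(h2 = 1), "h2")
  spec <- asthma_cluster_spec()
  spec$prop <- spec$prop * 2
  expect_error(sim_config(cluster_spec = spec), "proportions")
  spec2 <- asthma_cluster_spec()
  spec2$onset_sd[2] <- 0
  expect_error(sim_config(cluster_spec = spec2), "SD")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_controls = 60, n_cases = 30, n_snps = 100, n_blocks = 10, seed = 5)
  a <- simulate_reference_panel(cfg)
  b <- simulate_reference_panel(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$truth$causal, b$truth$causal)
  ca <- simulate_asthma_cohort(cfg, a$truth)
  cb <- simulate_asthma_cohort(cfg, a$truth)
  expect_identical(ca$genotypes$dosage, cb$genotypes$dosage)
  expect_identical(ca$cohort, cb$cohort)
})

test_that("block_corr = 0 gives independent adjacent SNPs", {
  cfg <- sim_config(
    n_controls = 500, n_cases = 0, n_snps = 1000, n_blocks = 50,
    block_corr = 0, missing_rate = 0, seed = 2
  )
  d <- simulate_reference_panel(cfg)$genotypes$dosage
  r <- vapply(seq_len(999), function(j) cor(d[, j], d[, j + 1]), numeric(1))
  expect_lt(mean(abs(r)), 0.05)
})

test_that("single-SNP genotype frequencies follow Hardy-Weinberg binomial sampling", {
  cfg <- sim_config(
    n_controls = 2000, n_cases = 0, n_snps = 1, n_blocks = 1,
    maf_range = c(0.3, 0.3), missing_rate = 0, n_causal = 0, seed = 3
  )
  d <- simulate_reference_panel(cfg)$genotypes$dosage
  # expected (p0, p1, p2) = (0.49, 0.42, 0.09) for maf 0.3
  expected <- c(0.49, 0.42, 0.09)
  obs <- c(mean(d == 0), mean(d == 1), mean(d == 2))
  tol <- 3 * sqrt(expected * (1 - expected) / 2000)
  expect_true(all(abs(obs - expected) < tol))
})

test_that("per-SNP Hardy-Weinberg holds before artifact injection", {
  cfg <- sim_config(
    n_controls = 500, n_cases = 0, n_snps = 10000, n_blocks = 500,
    missing_rate = 0, seed = 4
  )
  d <- simulate_reference_panel(cfg)$genotypes$dosage
  p <- hwe_exact_test(
    colSums(d == 0), colSums(d == 1), colSums(d == 2)
  )
  expect_lt(mean(p < 1e-6), 0.001)
})

test_that("phenotype construction recovers its own generative slope and scale", {
  # zero effects: phenotype SD is the configured noise SD (0.58 scale)
  cfg0 <- sim_config(
    n_controls = 1287, n_cases = 0, n_snps = 200, n_blocks = 20,
    h2 = 0, n_causal = 0, seed = 6,
    covariate_effects = c(
      age = 0, sex_male = 0, smoking_0_10 = 0, smoking_gt10 = 0, atopy = 0
    )
  )
  ref0 <- simulate_reference_panel(cfg0)
  coh0 <- simulate_phenotypes(ref0$genotypes, ref0$truth, cfg0)
  expect_gt(sd(coh0$log_ige), 0.55)
  expect_lt(sd(coh0$log_ige), 0.61)
  expect_equal(sd(coh0$genetic_value), 0) # h2 = 0 -> no genetic signal

  # h2 = 0.4: regression of phenotype on true genetic value has slope 1
  cfg1 <- sim_config(
    n_controls = 2000, n_cases = 0, n_snps = 1000, n_blocks = 100,
    h2 = 0.4, n_causal = 40, seed = 7
  )
  ref1 <- simulate_reference_panel(cfg1)
  coh1 <- simulate_phenotypes(ref1$genotypes, ref1$truth, cfg1)
  fit <- summary(lm(log_ige ~ genetic_value, data = coh1))
  slope <- fit$coefficients["genetic_value", ]
  expect_lt(abs(slope["Estimate"] - 1), 2 * slope["Std. Error"])
})

test_that("mismatched sample ids are rejected", {
  cfg <- sim_config(n_controls = 30, n_cases = 0, n_snps = 50, n_blocks = 5, seed = 1)
  ref <- simulate_reference_panel(cfg)
  other <- ref$genotypes
  rownames(other$dosage) <- paste0("X", seq_len(30))
  bad_truth <- ref$truth
  bad_truth$causal$snp[1] <- "rs_not_there"
  expect_error(simulate_phenotypes(other, bad_truth, cfg), "missing")
})

test_that("planted case components have the specified counts and means", {
  spec <- asthma_cluster_spec(
    onset_mean = c(49, 10, 49, 55), prop = rep(0.25, 4)
  )
  fe <- simulate_cluster_features(spec, n = 800, seed = 9)
  counts <- table(fe$cluster_truth)
  tol_n <- 3 * sqrt(800 * 0.25 * 0.75)
  expect_true(all(abs(counts - 200) < tol_n))
  for (k in 1:4) {
    v <- fe$onset_age[fe$cluster_truth == k]
    expect_lt(
      abs(mean(v) - spec$onset_mean[k]),
      2 * spec$onset_sd[k] / sqrt(length(v))
    )
  }
})

test_that("truth labels separate planted components (silhouette)", {
  # components separated by two pooled SDs along each discriminating
  # feature (cyclic +2/-2 pattern)
  spec <- asthma_cluster_spec(
    prs_z_mean = c(2, 0, 0, -2), prs_z_sd = rep(1, 4),
    log_ige_mean = c(-2, 2, 0, 0), log_ige_sd = rep(1, 4),
    onset_mean = 50 + c(0, -2, 2, 0), onset_sd = rep(1, 4),
    pfev1_mean = c(0, 0, -2, 2), pfev1_sd = rep(1, 4),
    prop = rep(0.25, 4)
  )
  fe <- simulate_cluster_features(spec, n = 600, seed = 10)
  sil <- silhouette_index(
    fe[c("prs_z", "log_ige", "onset_age", "pfev1")], fe$cluster_truth
  )
  expect_gte(sil, 0.3)
})

test_that("asthma cohort carries the planted burden gradient in genotypes", {
  cfg <- sim_config(
    n_controls = 50, n_cases = 400, n_snps = 1000, n_blocks = 100,
    h2 = 0.3, n_causal = 30, seed = 11
  )
  ref <- simulate_reference_panel(cfg)
  cases <- simulate_asthma_cohort(cfg, ref$truth)
  gv <- igeprs:::.genetic_value(cases$genotypes, ref$truth)
  m <- tapply(gv, cases$cohort$cluster_truth, mean)
  expect_true(m[["1"]] > m[["2"]], m[["2"]] > m[["3"]])
  expect_gt(m[["1"]], m[["4"]])
})

test_that("artifact injection produces exactly the requested defects", {
  g <- binom_geno(50, 400, maf = 0.3, seed = 12)
  expect_identical(inject_artifacts(g, list()), g)
  ids <- c("S003", "S017", "S042")
  g2 <- inject_artifacts(g, list(missing = list(ids = ids, rate = 0.15)), seed = 1)
  miss <- rowMeans(is.na(g2$dosage))
  expect_setequal(names(miss[miss > 0.10]), ids)
  g3 <- inject_artifacts(
    g, list(duplicates = c(DUP = "S001"), offspring = c(KID = "S002")),
    seed = 2
  )
  expect_true(all(c("DUP", "KID") %in% sample_ids(g3)))
  expect_error(
    inject_artifacts(g, list(missing = list(ids = "NOPE"))), "NOPE"
  )
})
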