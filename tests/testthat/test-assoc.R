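test_that("PC1 separates two subpopulations with diverged allele frequencies", {
  set.seed(31)
  n <- 200
  m <- 1000
  pop <- rep(c(0, 1), each = n / 2)
  p1 <- runif(m, 0.15, 0.5)
  p2 <- pmin(pmax(p1 + sample(c(-0.2, 0.2), m, TRUE), 0.02), 0.98)
  d <- t(vapply(seq_len(n), function(i) {
    p <- if (pop[i] == 0) p1 else p2
    rbinom(m, 2, p)
  }, numeric(m)))
  g <- as_geno(d)
  pca <- genotype_pca(g, k = 2)
  r <- cor(pca$scores$PC1, pop)
  expect_gt(abs(r), 0.9)
})

test_that("k = 0 yields an empty score set", {
  g <- binom_geno(30, 50, seed = 32)
  pca <- genotype_pca(g, k = 0)
  expect_identical(names(pca$scores), "sample")
  proj <- project_pca(pca, g)
  expect_identical(names(proj), "sample")
})

test_that("PCA scores match a dense eigendecomposition oracle", {
  set.seed(33)
  d <- matrix(sample(0:2, 20, TRUE), 5, 4)
  d[1, 2] <- NA
  g <- as_geno(d)
  pca <- genotype_pca(g, k = 2)
  # oracle: standardize identically, full SVD
  p <- colMeans(d, na.rm = TRUE) / 2
  x <- sweep(d, 2, 2 * p)
  x[is.na(x)] <- 0
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(x)
  oracle <- sv$u[, 1:2] %*% diag(sv$d[1:2])
  got <- as.matrix(pca$scores[, c("PC1", "PC2")])
  for (j in 1:2) {
    expect_true(
      max(abs(got[, j] - oracle[, j])) < 1e-8 ||
        max(abs(got[, j] + oracle[, j])) < 1e-8
    )
  }
  # component means are zero and components orthogonal
  expect_lt(max(abs(colMeans(got))), 1e-10)
  expect_lt(abs(crossprod(got[, 1], got[, 2])), 1e-8)
  # projecting the fitting samples reproduces the scores
  proj <- project_pca(pca, g)
  expect_equal(as.matrix(proj[, -1]), got, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("quantitative GWAS handles exact, degenerate and undefined fits", {
  d <- cbind(snp1 = c(0, 1, 2, 1, 0, 2, 1, 1), flat = rep(1, 8))
  g <- as_geno(d)
  y <- d[, 1] + 5
  res <- gwas_quantitative(g, y)
  expect_equal(res$beta[1], 1, tolerance = 1e-12)
  expect_true(res$degenerate[1])
  expect_lt(res$p[1], 1e-300)
  expect_true(is.na(res$beta[2])) # zero-variance SNP
})

test_that("quantitative GWAS equals the closed-form OLS oracle", {
  set.seed(34)
  n <- 8
  d <- matrix(sample(0:2, n * 3, TRUE), n)
  g <- as_geno(d)
  y <- rnorm(n)
  cov <- data.frame(cv = rnorm(n))
  res <- gwas_quantitative(g, y, cov)
  for (j in 1:3) {
    o <- ols_oracle(y, cbind(1, cov$cv, d[, j]))
    expect_equal(res$beta[j], o$beta[3], tolerance = 1e-10)
    expect_equal(res$se[j], o$se[3], tolerance = 1e-10)
    expect_equal(res$p[j], 2 * pt(-abs(o$beta[3] / o$se[3]), o$df), tolerance = 1e-10)
  }
  # missing-dosage path agrees with lm() on the complete subset
  d2 <- d
  d2[c(2, 5), 1] <- NA
  g2 <- as_geno(d2)
  res2 <- gwas_quantitative(g2, y, cov)
  obs <- !is.na(d2[, 1])
  fit <- summary(lm(y[obs] ~ cov$cv[obs] + d2[obs, 1]))
  expect_equal(res2$beta[1], unname(fit$coefficients[3, 1]), tolerance = 1e-10)
  expect_equal(res2$se[1], unname(fit$coefficients[3, 2]), tolerance = 1e-10)
})

test_that("collinear covariates raise an error naming the column", {
  g <- binom_geno(20, 5, seed = 35)
  y <- rnorm(20)
  cov <- data.frame(a = 1:20, b = 2 * (1:20))
  expect_error(gwas_quantitative(g, y, cov), "b")
})

test_that("null quantitative GWAS p-values are uniform", {
  sim <- small_logo_cohort(n = 300, n_snps = 2000, h2 = 0.3, seed = 36)
  y_perm <- withr::with_seed(99, sample(sim$cohort$log_ige))
  res <- gwas_quantitative(sim$genotypes, y_perm)
  ks <- suppressWarnings(stats::ks.test(res$p[!is.na(res$p)], "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("allelic case-control test matches the 2x2 chi-square oracle", {
  # cases: allele counts (120, 80); controls: (100, 100)
  d_cases <- c(rep(2, 20), rep(1, 80), rep(0, 0))
  d_ctrls <- rep(1, 100)
  d <- matrix(c(d_cases, d_ctrls), ncol = 1)
  g <- as_geno(d)
  labels <- c(rep(TRUE, 100), rep(FALSE, 100))
  res <- gwas_casecontrol(g, labels)
  oracle <- chisq.test(
    rbind(c(120, 80), c(100, 100)),
    correct = FALSE
  )
  expect_equal(res$p[1], oracle$p.value, tolerance = 1e-12)
  expect_equal(res$beta[1], log((120 * 100) / (80 * 100)), tolerance = 1e-12)

  # identical allele frequencies -> statistic 0, p = 1
  d_eq <- matrix(rep(c(0, 1, 2, 1), 10), ncol = 1)
  g_eq <- as_geno(d_eq)
  res_eq <- gwas_casecontrol(g_eq, rep(c(TRUE, FALSE), 20))
  expect_equal(res_eq$p[1], 1, tolerance = 1e-12)

  expect_error(gwas_casecontrol(g, rep(FALSE, 200)), "non-empty")
})

test_that("lead-SNP selection is greedy and matches the brute-force oracle", {
  g0 <- binom_geno(50, 3, seed = 37)
  s0 <- gwas_quantitative(g0, rnorm(50))
  s0$p <- c(0.5, 0.9, 0.2)
  expect_length(select_lead_snps(s0, g0), 0)
  s0$p <- c(5e-6, 0.9, 0.2)
  expect_identical(select_lead_snps(s0, g0), s0$snp[1])

  for (seed in 1:5) {
    set.seed(seed + 40)
    n <- 100
    g <- simulate_reference_panel(sim_config(
      n_controls = n, n_cases = 0, n_snps = 20, n_blocks = 4,
      n_causal = 0, block_corr = 0.8, missing_rate = 0, seed = seed
    ))$genotypes
    stats <- gwas_quantitative(g, rnorm(n))
    stats$p <- 10^runif(20, -8, 0)
    got <- select_lead_snps(stats, g, p_max = 1e-2, r2_max = 0.1, window_kb = 10)
    oracle <- greedy_select_oracle(stats, g,
      p_max = 1e-2, r2_max = 0.1,
      window_kb = 10, strict = TRUE
    )
    expect_identical(got, oracle)
    # mutual independence of the lead set
    if (length(got) > 1) {
      for (i in seq_along(got)) {
        for (j in seq_len(i - 1)) {
          pi <- stats$pos[stats$snp == got[i]]
          pj <- stats$pos[stats$snp == got[j]]
          if (abs(pi - pj) <= 10 * 1000) {
            r2 <- suppressWarnings(
              cor(g$dosage[, got[i]], g$dosage[, got[j]])^2
            )
            expect_lt(r2, 0.1)
          }
        }
      }
    }
  }
})
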