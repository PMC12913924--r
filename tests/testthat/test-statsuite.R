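test_that("chi-square independence equals brute force and the stats oracle", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      m <- matrix(rpois(12, 40) + 1, 3, 4)
    })
    got <- chi_square_independence(m)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(got$statistic, sum((m - e)^2 / e), tolerance = 1e-10)
    oracle <- chisq.test(m, correct = FALSE)
    expect_equal(got$statistic, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(got$p, oracle$p.value, tolerance = 1e-10)
  }
  # proportional rows: statistic 0, p = 1
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  got0 <- chi_square_independence(prop)
  expect_equal(got0$statistic, 0, tolerance = 1e-12)
  expect_equal(got0$p, 1)
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "row 1")
  expect_error(chi_square_independence(rbind(c(1, 0), c(2, 0))), "column 2")
})

test_that("Kruskal-Wallis is rank-based and monotone-transform invariant", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  got <- kruskal_wallis(same)
  expect_equal(got$statistic, 0, tolerance = 1e-12)
  expect_equal(got$p, 1)

  withr::with_seed(7, {
    groups <- list(a = rlnorm(20), b = rlnorm(25, 0.4), c = rlnorm(15, 0.8))
  })
  raw <- kruskal_wallis(groups)
  logged <- kruskal_wallis(lapply(groups, log))
  expect_equal(raw$statistic, logged$statistic, tolerance = 1e-12)
  expect_equal(raw$p, logged$p, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(a = 1:3)), "2 groups")
})

test_that("Kruskal-Wallis p matches a permutation oracle on a small instance", {
  groups <- list(a = c(1.2, 3.4, 0.7, 2.2), b = c(4.1, 5.0, 3.9, 4.4), c = c(2.0, 1.1, 2.8, 0.9))
  got <- kruskal_wallis(groups)
  x <- unlist(groups)
  g <- rep(1:3, each = 4)
  h_obs <- kw_h_oracle(x, g)
  expect_equal(got$statistic, h_obs, tolerance = 1e-10)
  n_perm <- 100000
  withr::with_seed(8, {
    exceed <- vapply(seq_len(n_perm), function(i) {
      kw_h_oracle(x, sample(g)) >= h_obs - 1e-12
    }, logical(1))
  })
  p_perm <- mean(exceed)
  # chi-square approximation within Monte-Carlo + approximation error
  mc_se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(got$p - p_perm), 0.02 + 3 * mc_se)
})

test_that("Dunn z follows the tie-corrected formula with Bonferroni capping", {
  withr::with_seed(9, {
    groups <- list(
      g1 = round(rnorm(12, 0, 1), 1),
      g2 = round(rnorm(15, 0.8, 1), 1),
      g3 = round(rnorm(10, 1.6, 1), 1)
    )
  })
  got <- dunn_bonferroni(groups)
  expect_equal(nrow(got), 3L)
  for (r in seq_len(3)) {
    i <- match(got$group1[r], names(groups))
    j <- match(got$group2[r], names(groups))
    expect_equal(got$z[r], dunn_z_oracle(groups, i, j), tolerance = 1e-10)
    # antisymmetry under pair order swap
    expect_equal(dunn_z_oracle(groups, j, i), -got$z[r], tolerance = 1e-10)
  }
  expect_equal(got$p_adj, pmin(1, got$p * 3), tolerance = 1e-12)

  # two groups: a single pair, adjusted p equals raw p
  two <- dunn_bonferroni(groups[1:2])
  expect_equal(two$p_adj, two$p)
})

test_that("covariate-adjusted comparison reduces to the mean difference under orthogonality", {
  y <- c(1, 2, 3, 4, 10, 11, 12, 13)
  grp <- c(0, 0, 0, 0, 1, 1, 1, 1)
  cov <- data.frame(c1 = c(-1, 1, -1, 1, -1, 1, -1, 1)) # orthogonal to group
  got <- adjusted_group_comparison(y, grp, cov)
  expect_equal(got$beta, mean(y[grp == 1]) - mean(y[grp == 0]), tolerance = 1e-10)

  # fixed 10-row instance against the normal-equations oracle
  withr::with_seed(10, {
    y2 <- rnorm(10)
    g2 <- rbinom(10, 1, 0.5)
    c2 <- data.frame(a = rnorm(10), b = rnorm(10))
  })
  got2 <- adjusted_group_comparison(y2, g2, c2)
  o <- ols_oracle(y2, cbind(1, g2, c2$a, c2$b))
  expect_equal(got2$beta, unname(o$beta[2]), tolerance = 1e-10)
  expect_equal(got2$se, unname(o$se[2]), tolerance = 1e-10)
})

test_that("permuted group labels give uniform p-values", {
  withr::with_seed(11, {
    y <- rnorm(60)
    cov <- data.frame(a = rnorm(60))
    ps <- vapply(seq_len(2000), function(i) {
      adjusted_group_comparison(y, sample(rep(0:1, 30)), cov)$p
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("Pearson r-squared matches the direct formula", {
  x <- c(-1, 0, 1)
  expect_equal(pearson_r2(x, x + 2)$r2, 1, tolerance = 1e-12)
  expect_equal(pearson_r2(x, c(1, -2, 1))$r2, 0, tolerance = 1e-12)
  withr::with_seed(12, {
    a <- rnorm(6)
    b <- 0.5 * a + rnorm(6)
  })
  got <- pearson_r2(a, b)
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r2, r^2, tolerance = 1e-12)
  ct <- stats::cor.test(a, b)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)
  expect_error(pearson_r2(rep(1, 5), rnorm(5)), "constant")
})

test_that("the normality/variance gate routes as designed", {
  # clean normal groups: the gate passes four alpha = 0.05 tests (three
  # Shapiro-Wilk, one Levene), so the parametric rate is about
  # 0.95^4 = 0.81; check it sits in that type-I band
  dec <- vapply(1:100, function(s) {
    withr::with_seed(1000 + s, {
      g <- list(a = rnorm(200), b = rnorm(200), c = rnorm(200))
    })
    normality_variance_gate(g)$decision
  }, character(1))
  expect_gte(mean(dec == "parametric"), 0.70)
  expect_lte(mean(dec == "parametric"), 0.93)

  # heavy right skew: nonparametric in at least 99% of seeds
  dec2 <- vapply(1:100, function(s) {
    withr::with_seed(2000 + s, {
      g <- list(a = rlnorm(200, sdlog = 1.5), b = rnorm(200))
    })
    normality_variance_gate(g)$decision
  }, character(1))
  expect_gte(mean(dec2 == "nonparametric"), 0.99)

  # a group of size 2 routes nonparametric with a reason
  small <- normality_variance_gate(list(a = c(1, 2), b = rnorm(10)))
  expect_equal(small$decision, "nonparametric")
  expect_match(small$reason, "small")
})
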