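test_that("fold assignment is a balanced, reproducible partition", {
  ids <- sprintf("C%04d", 1:1287)
  f <- make_folds(ids, k = 5, seed = 3)
  expect_setequal(as.integer(table(f$fold)), c(258L, 258L, 257L, 257L, 257L))
  expect_identical(f, make_folds(ids, k = 5, seed = 3))
  expect_false(identical(f$fold, make_folds(ids, k = 5, seed = 4)$fold))
  expect_setequal(f$sample, ids)
  expect_error(make_folds(ids[1:3], k = 5), "<=")
})

test_that("the LOGO build yields K scores per sample and positive fold SEs", {
  sim <- small_logo_cohort(n = 300, n_snps = 600, h2 = 0.3, seed = 71)
  folds <- make_folds(sample_ids(sim$genotypes), k = 5, seed = 72)
  fit <- suppressWarnings(run_logo(sim$genotypes, sim$cohort, folds, k_pcs = 2))
  expect_equal(fit$k, 5)
  prs_cols <- paste0("prs_", 1:5)
  expect_true(all(prs_cols %in% names(fit$scores)))
  expect_false(anyNA(fit$scores[prs_cols]))
  expect_true(all(fit$folds$se > 0))
  expect_true(all(fit$folds$threshold %in% prs_threshold_grid()))
  expect_error(
    run_logo(sim$genotypes, sim$cohort,
      make_folds(sample_ids(sim$genotypes), k = 15, seed = 1)
    ),
    "smaller"
  )
})

test_that("inverse-variance combination follows the printed formula", {
  sc <- tibble::tibble(sample = c("a", "b"), prs_1 = c(1, 2), prs_2 = c(3, 2))
  # PRS (1, 3), SE (0.5, 1): (4*1 + 1*3) / 5 = 1.4
  out <- meta_combine(sc, fold_ses = c(0.5, 1))
  expect_equal(out$ige_prs[1], 1.4)
  # identical fold scores pass through whatever the SEs
  expect_equal(out$ige_prs[2], 2)
  # equal SEs give the arithmetic mean
  out_eq <- meta_combine(sc, fold_ses = c(2, 2))
  expect_equal(out_eq$ige_prs, c(2, 2))
  expect_error(meta_combine(sc, fold_ses = c(0, 1)), "positive")
  expect_error(meta_combine(sc, fold_ses = c(NA, 1)), "positive")
})

test_that("the combined score is a convex combination of fold scores", {
  withr::with_seed(73, {
    m <- matrix(rnorm(50 * 5), 50, 5)
    sc <- tibble::tibble(sample = as.character(1:50), !!!as.data.frame(m) |>
      setNames(paste0("prs_", 1:5)))
    ses <- runif(5, 0.2, 3)
  })
  out <- meta_combine(sc, fold_ses = ses)
  expect_true(all(out$ige_prs >= apply(m, 1, min) - 1e-12))
  expect_true(all(out$ige_prs <= apply(m, 1, max) + 1e-12))
})

test_that("reference standardization centers and scales exactly", {
  meta <- tibble::tibble(sample = as.character(1:100), ige_prs = rnorm(100, 3, 2))
  z <- zscore_reference(meta)
  expect_lt(abs(mean(z$scores$ige_prs_z)), 1e-10)
  expect_lt(abs(sd(z$scores$ige_prs_z) - 1), 1e-10)
  mu <- z$reference$mean
  sigma <- z$reference$sd
  z2 <- zscore_reference(
    tibble::tibble(sample = "x", ige_prs = mu + sigma),
    reference_ids = character(0)
  ) |> expect_error("empty")
  # an input at the reference mean maps to 0; at mean + sd maps to 1
  probe <- tibble::tibble(sample = c("p0", "p1"), ige_prs = c(mu, mu + sigma))
  both <- dplyr::bind_rows(meta, probe)
  z3 <- zscore_reference(both, reference_ids = meta$sample)
  expect_equal(z3$scores$ige_prs_z[z3$scores$sample == "p0"], 0, tolerance = 1e-12)
  expect_equal(z3$scores$ige_prs_z[z3$scores$sample == "p1"], 1, tolerance = 1e-12)
  degenerate <- tibble::tibble(sample = c("a", "b"), ige_prs = c(1, 1))
  expect_error(zscore_reference(degenerate), "zero SD")
})

test_that("held-out association does not exceed in-sample association on average", {
  diffs <- vapply(1:10, function(s) {
    sim <- small_logo_cohort(n = 500, n_snps = 500, h2 = 0.3, seed = 200 + s)
    folds <- make_folds(sample_ids(sim$genotypes), k = 5, seed = 300 + s)
    fit <- suppressWarnings(run_logo(sim$genotypes, sim$cohort, folds, k_pcs = 0))
    ids <- fit$scores$sample
    y <- sim$cohort$log_ige[match(ids, sim$cohort$sample)]
    r2 <- function(yy, prs) summary(lm(yy ~ prs))$r.squared
    in_sample <- held_out <- numeric(fit$k)
    for (i in seq_len(fit$k)) {
      own <- fit$scores$fold == i
      held_out[i] <- r2(y[own], fit$scores[[paste0("prs_", i)]][own])
      in_sample[i] <- r2(y[!own], fit$scores[[paste0("prs_", i)]][!own])
    }
    mean(in_sample) - mean(held_out)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("external samples with identical genotypes get identical z-scores", {
  sim <- small_logo_cohort(n = 250, n_snps = 500, h2 = 0.3, seed = 74)
  folds <- make_folds(sample_ids(sim$genotypes), k = 5, seed = 75)
  fit <- suppressWarnings(run_logo(sim$genotypes, sim$cohort, folds, k_pcs = 0))
  z <- zscore_reference(meta_combine(fit))
  # clone three reference samples as an "external" cohort
  pick <- sample_ids(sim$genotypes)[c(3, 50, 111)]
  ext_d <- sim$genotypes$dosage[pick, , drop = FALSE]
  rownames(ext_d) <- paste0("EXT", 1:3)
  ext <- geno_matrix(ext_d, sim$genotypes$snps)
  got <- suppressWarnings(apply_to_external(fit, NULL, ext, z$reference))
  expect_equal(
    got$ige_prs_z,
    z$scores$ige_prs_z[match(pick, z$scores$sample)],
    tolerance = 1e-12
  )
  expect_error(apply_to_external(list(), numeric(0), ext, z$reference), "non-empty")
})

test_that("scores transfer to an external cohort drawn from the same causal model", {
  cfg <- sim_config(
    n_controls = 500, n_cases = 0, n_snps = 1000, n_blocks = 50,
    h2 = 0.35, n_causal = 25, seed = 76, missing_rate = 0.002
  )
  ref <- simulate_reference_panel(cfg)
  coh <- simulate_phenotypes(ref$genotypes, ref$truth, cfg)
  folds <- make_folds(sample_ids(ref$genotypes), k = 5, seed = 77)
  fit <- suppressWarnings(run_logo(ref$genotypes, coh, folds, k_pcs = 0))
  z <- zscore_reference(meta_combine(fit))
  # external draw from the same panel and causal effects
  ext_ids <- sprintf("E%04d", 1:500)
  ext_d <- withr::with_seed(
    78,
    igeprs:::.sim_geno_from_panel(ref$truth$panel, cfg$block_corr, ext_ids)
  )
  ext_g <- geno_matrix(ext_d, ref$genotypes$snps)
  ext_coh <- simulate_phenotypes(ext_g, ref$truth, cfg, seed = 79)
  got <- suppressWarnings(apply_to_external(fit, NULL, ext_g, z$reference))
  ct <- stats::cor.test(got$ige_prs_z, ext_coh$log_ige)
  expect_gt(unname(ct$estimate), 0)
  expect_lt(ct$p.value, 0.01)
})
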