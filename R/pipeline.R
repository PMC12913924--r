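#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end run: simulation, QC, the LOGO
#' PRS build, clustering, and output location. All stage seeds derive from
#' the single `seed`.
#'
#' @param seed Master seed.
#' @param sim A [sim_config()] (its seed is overridden by `seed`).
#' @param qc A [qc_config()].
#' @param k_folds LOGO fold count (default 5).
#' @param k_pcs Genetic principal components per fold.
#' @param r2_max,window_kb Clumping parameters.
#' @param grid P-value threshold grid.
#' @param k_max Maximum cluster count.
#' @param stages Stages to run, in order, a subset of
#'   `c("simulate", "qc", "logo", "external", "cluster", "centroid",
#'   "stats")`. Later stages require their upstream stages.
#' @param out_dir Optional output directory; when set, every stage writes
#'   its artifact files there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            qc = qc_config(),
                            k_folds = 5L, k_pcs = 5L,
                            r2_max = 0.1, window_kb = 250,
                            grid = prs_threshold_grid(),
                            k_max = 15L,
                            stages = c(
                              "simulate", "qc", "logo", "external",
                              "cluster", "centroid", "stats"
                            ),
                            out_dir = NULL) {
  all_stages <- c("simulate", "qc", "logo", "external", "cluster", "centroid", "stats")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  sim$seed <- as.integer(seed)
  structure(
    list(
      seed = as.integer(seed), sim = sim, qc = qc,
      k_folds = k_folds, k_pcs = k_pcs, r2_max = r2_max,
      window_kb = window_kb, grid = grid, k_max = k_max,
      stages = stages, out_dir = out_dir,
      hash = rlang::hash(list(seed, sim[names(sim) != "cluster_spec"], k_folds, k_pcs, r2_max, window_kb, grid, k_max))
    ),
    class = "pipeline_config"
  )
}

.stage_requires <- function(config, stage, needed, artifacts) {
  for (nm in needed) {
    if (is.null(artifacts[[nm]])) {
      abort(paste0(
        "stage '", stage, "' requires the '", nm,
        "' stage output, which was not run or provided."
      ))
    }
  }
}

#' Run the full study pipeline on a synthetic cohort
#'
#' Executes, in order: cohort simulation, quality control (controls then
#' cases), the leave-one-group-out PRS build on controls, external scoring
#' of cases, two-step clustering of cases on (IgE_PRS z, log IgE, onset
#' age, pFEV1), centroid-model fitting with nearest-centroid
#' self-assignment, and the comparison statistics battery. Any subset of
#' stages may be selected; a stage whose inputs are absent halts with the
#' stage name.
#'
#' @param config A [pipeline_config()].
#' @return A named list of stage artifacts: `truth`, `genotypes_controls`,
#'   `cohort_controls`, `genotypes_cases`, `cohort_cases`, `qc`,
#'   `logo`, `scores` (controls, with z), `reference`, `external` (case
#'   scores), `cluster`, `centroid`, `assignments`, `stats`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  art <- list(config = config)
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
    })
  }
  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      ref <- simulate_reference_panel(config$sim)
      art$truth <<- ref$truth
      art$genotypes_controls <<- ref$genotypes
      art$cohort_controls <<- simulate_phenotypes(ref$genotypes, ref$truth, config$sim)
      if (config$sim$n_cases > 0) {
        cases <- simulate_asthma_cohort(config$sim, ref$truth)
        art$genotypes_cases <<- cases$genotypes
        art$cohort_cases <<- cases$cohort
      }
      if (!is.null(out)) {
        write_cohort(art$cohort_controls, file.path(out, "cohort_controls.tsv"),
          seed = config$seed
        )
        if (!is.null(art$cohort_cases)) {
          write_cohort(art$cohort_cases, file.path(out, "cohort_cases.tsv"),
            seed = config$seed
          )
        }
      }
    })
  }
  if ("qc" %in% config$stages) {
    run_stage("qc", function() {
      .stage_requires(config, "qc", "genotypes_controls", art)
      qc_ctrl <- run_qc(art$genotypes_controls, config$qc)
      art$genotypes_controls <<- qc_ctrl$genotypes
      art$cohort_controls <<- dplyr::semi_join(
        art$cohort_controls,
        tibble::tibble(sample = sample_ids(qc_ctrl$genotypes)),
        by = "sample"
      )
      art$qc <<- list(controls = qc_ctrl[c("samples", "snps")])
      if (!is.null(art$genotypes_cases)) {
        samp <- sample_qc(art$genotypes_cases, config$qc)
        keep <- samp$sample[!samp$excluded]
        g1 <- geno_subset(art$genotypes_cases, samples = keep)
        kin <- kinship_matrix(g1, min_kinship = config$qc$kinship_threshold)
        rel <- kinship_filter(kin, g1, threshold = config$qc$kinship_threshold)
        keep <- setdiff(keep, rel$sample)
        # cases restricted to the SNPs that survived control-side SNP QC
        art$genotypes_cases <<- geno_subset(art$genotypes_cases,
          samples = keep, snps = snp_ids(qc_ctrl$genotypes)
        )
        art$cohort_cases <<- dplyr::semi_join(
          art$cohort_cases, tibble::tibble(sample = keep),
          by = "sample"
        )
        art$qc$cases <<- list(samples = samp, related = rel)
      }
      if (!is.null(out)) {
        .write_tsv_with_header(
          qc_ctrl$samples, file.path(out, "qc_samples_controls.tsv"),
          seed = config$seed, extra = paste0("config=", config$hash)
        )
        .write_tsv_with_header(
          qc_ctrl$snps, file.path(out, "qc_snps_controls.tsv"),
          seed = config$seed, extra = paste0("config=", config$hash)
        )
      }
    })
  }
  if ("logo" %in% config$stages) {
    run_stage("logo", function() {
      .stage_requires(config, "logo", c("genotypes_controls", "cohort_controls"), art)
      folds <- make_folds(sample_ids(art$genotypes_controls),
        k = config$k_folds, seed = config$seed + 10L
      )
      fit <- run_logo(art$genotypes_controls, art$cohort_controls, folds,
        k_pcs = config$k_pcs, r2_max = config$r2_max,
        window_kb = config$window_kb, grid = config$grid
      )
      art$logo <<- fit
      meta <- meta_combine(fit)
      z <- zscore_reference(meta)
      art$scores <<- z$scores
      art$reference <<- z$reference
      if (!is.null(out)) {
        .write_tsv_with_header(
          dplyr::left_join(fit$scores, z$scores, by = "sample"),
          file.path(out, "scores_controls.tsv"),
          seed = config$seed, extra = paste0("config=", config$hash)
        )
        write_prs_model(fit$models, file.path(out, "fold_models.json"))
        .write_tsv_with_header(fit$folds, file.path(out, "folds.tsv"),
          seed = config$seed
        )
      }
    })
  }
  if ("external" %in% config$stages) {
    run_stage("external", function() {
      .stage_requires(config, "external", c("logo", "reference", "genotypes_cases"), art)
      ext <- apply_to_external(
        art$logo, NULL, art$genotypes_cases, art$reference
      )
      art$external <<- ext
      if (!is.null(out)) {
        .write_tsv_with_header(ext, file.path(out, "scores_cases.tsv"),
          seed = config$seed, extra = paste0("config=", config$hash)
        )
      }
    })
  }
  if ("cluster" %in% config$stages) {
    run_stage("cluster", function() {
      .stage_requires(config, "cluster", c("external", "cohort_cases"), art)
      feats <- dplyr::inner_join(
        dplyr::select(art$external, "sample", "ige_prs_z"),
        dplyr::select(
          art$cohort_cases, "sample", "log_ige", "onset_age", "pfev1"
        ),
        by = "sample"
      )
      art$cluster_features <<- feats
      art$cluster <<- twostep_cluster(feats,
        k_max = config$k_max,
        seed = config$seed + 20L
      )
      if (!is.null(out)) {
        .write_tsv_with_header(
          art$cluster$labels, file.path(out, "cluster_labels.tsv"),
          seed = config$seed, extra = paste0("config=", config$hash)
        )
        jsonlite::write_json(
          list(
            k = art$cluster$k,
            standardization = art$cluster$standardization,
            centers = art$cluster$centers,
            bic = art$cluster$bic,
            silhouette = art$cluster$silhouette
          ),
          file.path(out, "cluster_model.json"),
          auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
        )
      }
    })
  }
  if ("centroid" %in% config$stages) {
    run_stage("centroid", function() {
      .stage_requires(config, "centroid", "cluster", art)
      art$centroid <<- as_centroid_model(art$cluster)
      art$assignments <<- assign_nearest(art$centroid, art$cluster_features)
      if (!is.null(out)) {
        .write_tsv_with_header(
          art$assignments, file.path(out, "centroid_assignments.tsv"),
          seed = config$seed, extra = paste0("config=", config$hash)
        )
      }
    })
  }
  if ("stats" %in% config$stages) {
    run_stage("stats", function() {
      .stage_requires(config, "stats", c("scores", "cohort_controls"), art)
      sc <- art$scores
      ctrl <- dplyr::inner_join(sc, art$cohort_controls, by = "sample")
      res <- list(
        prs_ige = pearson_r2(ctrl$ige_prs_z, ctrl$log_ige)
      )
      if (!is.null(art$cluster)) {
        feats <- dplyr::inner_join(
          art$cluster_features, art$cluster$labels,
          by = "sample"
        )
        grp <- c(
          split(feats$ige_prs_z, paste0("cluster", feats$cluster)),
          list(controls = ctrl$ige_prs_z)
        )
        res$gate <- normality_variance_gate(grp)
        res$kruskal <- kruskal_wallis(grp)
        res$dunn <- dunn_bonferroni(grp)
      }
      art$stats <<- res
      if (!is.null(out)) {
        jsonlite::write_json(res, file.path(out, "stats.json"),
          auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
        )
      }
    })
  }
  art
}
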