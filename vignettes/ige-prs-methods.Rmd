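---
title: "Leave-one-group-out IgE polygenic scores and asthma phenotype clustering: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(igeprs)
```

`igeprs` builds a polygenic risk score (PRS) for total serum IgE inside a
single cohort, without an external discovery GWAS, and uses it together
with clinical variables to dissect asthma heterogeneity. This vignette
explains the models, every tunable that matters, the synthetic data the
package tests itself on, and the method's known weaknesses.

## The LOGO score

The reference cohort (non-asthmatic controls) is split uniformly at random
into K = 5 subgroups (`make_folds()`; sizes differ by at most one). For
each fold *i*:

1. **GWAS on the base set** (the other four subgroups): per SNP, ordinary
   least squares of log10 IgE on effect-allele dosage plus covariates —
   age (years), sex, smoking pack-year category (two indicators against
   never-smokers), atopy, and `k_pcs = 5` genetic principal components.
   PCs are computed on the base samples only (dosages centered at 2p̂ and
   scaled by √(2p̂(1−p̂)), missing set to 0 after centering) and
   *projected* onto the held-out samples, so no information leaks through
   the covariates. The dosage coefficient, its standard error and a
   t-based p-value form the summary statistics.
2. **Clumping** (`ld_clump()`): greedy by ascending p; each retained index
   SNP removes SNPs within 250 kb whose dosage r² with it is ≥ 0.1. Ties
   on p break by position then id, so the output is independent of row
   order. These defaults are the conventional lead-SNP settings; both are
   arguments.
3. **Threshold selection** (`optimize_threshold()`): for each candidate
   threshold in {5e-8, 1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4,
   0.5, 1}, the held-out subgroup is scored and the incremental R² of the
   score over the covariate-only regression is recorded; the maximizing
   threshold wins. Thresholds that retain no SNP are skipped. Selecting on
   the *held-out* subgroup keeps the selection out-of-sample for that
   fold's weights.
4. **Scoring**: every individual is scored with the fold model,
   `PRS_j = (1/M_j) Σ_i S_i G_ij` — the average, not the sum, over the
   individual's non-missing scored SNPs (`M_j`), which makes scores
   comparable across individuals with different missingness. Alleles are
   reconciled by flipping dosage (G → 2 − G) when a model SNP's alleles
   are stored swapped; scoring is invariant to that flip.
5. **Fold weight**: the standard error of the PRS coefficient in the
   held-out covariate-adjusted regression of log-IgE on the fold score.
   Using the held-out (not in-sample) regression avoids rewarding
   overfit fold models with large weights.

The K scores are combined per individual by fixed-effect inverse-variance
weighting, `IgE_PRS = Σ PRS_i/SE_i² / Σ 1/SE_i²`, a convex combination of
the fold scores, and standardized against the reference cohort
(`zscore_reference()`), whose z-scores then have mean 0 and SD 1 exactly.
The same fold models, fold SEs and reference µ/σ are applied unchanged to
an external (asthma) cohort (`apply_to_external()`), which warns when a
fold model's SNP coverage drops below 90%.

**Leakage, stated plainly.** Because all individuals are scored with all K
models, each individual is in the GWAS base set of K − 1 of the K scores
that enter their combined value. The held-out threshold selection and the
held-out SE weights limit, but do not remove, the resulting in-sample
association. Under a zero-heritability simulation the combined score's R²
against the phenotype is typically below 0.02, but the distribution is
heavy-tailed: when a loose threshold happens to win the held-out
optimization, hundreds of noise SNPs enter a fold model and the combined
R² can reach ~0.1. The acceptance suite therefore checks the *median*
null R² over three runs. The practical implication is that headline R²
values from this design are somewhat optimistic; a fully honest
per-individual estimate would use only each individual's single held-out
score, at the cost of a noisier instrument.

## Quality control

Order of operations mirrors standard practice: sample filters, then
relatedness, then SNP filters, each threshold an argument of
`qc_config()`:

* missingness > 0.10 per sample;
* heterozygosity rate (het calls / non-missing calls) outside ±3 SD of
  the mean, both computed once over samples passing the missingness
  filter — no iteration, so QC of the kept set is stable;
* KING-robust kinship φ̂ = (N_both-het − 2·N_opposite-hom) /
  (N_het(i) + N_het(j)) over SNPs non-missing in both, with pairs above
  0.0884 (second-degree lower bound) flagged and the higher-missingness
  member removed (ties: the later sample). Duplicates sit near 0.5,
  parent–offspring near 0.25, unrelated near 0. The estimator's noise
  scales with the number of *independent* markers: with fewer than
  roughly 1,500 effective markers the 0.0884 threshold starts flagging
  unrelated pairs, which is why the scaled-down test pipelines use the
  first-degree bound 0.177. `run_qc()` thins to at most 5,000 SNPs for
  the kinship scan;
* SNP call rate < 0.99, minor allele frequency < 0.01 (from non-missing
  calls), exact Hardy–Weinberg p < 1e-6. The HWE test is the exact
  conditional test (sum of probabilities of heterozygote counts no more
  likely than the observed one, same parity, fixed allele counts),
  computed in log space with a 1 + 1e-10 relative guard on the
  ≤-comparison; it matches full enumeration to 1e-12 for all n ≤ 50. No
  mid-p variant.

## Two-step clustering

Cases are clustered on four features, in order: IgE_PRS z, log10 IgE
(IU/mL), asthma onset age (years), percent-predicted FEV1. Rows with any
missing feature are dropped (count reported). Features are standardized
(ML variances), because raw Euclidean/likelihood geometry would otherwise
be dominated by onset age and pFEV1.

* **Stage 1** assigns points sequentially (presentation order shuffled by
  the seed) to the nearest precluster by the log-likelihood distance
  d(a,b) = ξ_a + ξ_b − ξ_{a∪b} with
  ξ_v = −N_v Σ_d ½ log(σ̂²_d + σ̂²_vd), where σ̂²_d is the whole-sample
  variance (the regularizer that keeps log() finite for tight clusters).
  A point opens a new precluster when its best distance exceeds the
  current threshold; when the leaf budget (100) is exceeded the
  threshold grows to twice the closest current pair and the pass
  restarts. With n ≤ 100 distinct points, every point remains its own
  leaf and stage 2 is plain agglomeration.
* **Stage 2** agglomerates preclusters greedily by the same distance,
  recording each merge distance and the cluster map at every k.
  BIC(k) = −2 Σ_v ξ_v + 2·k·d·log N (one mean and one variance per
  cluster and feature) is evaluated along this path for k = 1..k_max.
* **Automatic k**: if BIC(2) ≥ BIC(1), k = 1. Otherwise the coarse pass
  takes k_init = the smallest k whose BIC-change ratio relative to the
  first change falls below 0.04; the refinement computes, for candidates
  2..k_init, the ratio of successive merge distances, and applies the
  two-candidates rule: the larger-k of the top two candidates wins when
  their ratios differ by less than 15%, otherwise the top candidate.
  One addition is load-bearing: the **homogeneity gate**. The
  classification-style likelihood above always improves when a Gaussian
  is split, so the BIC path alone never returns k = 1 on homogeneous
  data. A cluster structure is accepted only when the best
  merge-distance jump at least doubles the runner-up; smooth merge
  profiles (ratios near 1–1.7, which is what single-Gaussian data
  produce) yield k = 1. The factor 2 was fixed from the separation
  between homogeneous and clustered merge profiles on exploratory draws
  and is deliberately conservative: weak real structure (jump < 2) is
  reported as k = 1 rather than over-split.
* Labels are renumbered in descending order of the first feature's mean
  (the genetic score, by convention), and the mean silhouette (Euclidean
  on the standardized features; singletons contribute 0) is attached.

`twostep_bic()` recomputes BIC from any labeling for auditability, and
`k_select` forces a cut at a fixed k.

## Nearest-centroid classification

`fit_centroids()`/`as_centroid_model()` store per-cluster means in
standardized space together with the standardization itself — inherited
from the clustering build, never refit on new cases, so a new case is
projected into exactly the space the clusters were formed in. Distances
are Euclidean; ties go to the lowest cluster index (within 1e-12);
incomplete rows are reported unassigned. When built standalone, the
standardization uses population (ML) SDs, making centroids invariant
under duplicating the data set.

## The synthetic cohort generator

`sim_config()` defaults emulate the study conditions: 1,287 controls,
745 cases, 10,000 SNPs in 500 equicorrelated LD blocks (latent
haplotype-level correlation 0.7, thresholded to alleles — HWE holds per
SNP by construction, and the dichotomization attenuates the realized
dosage correlation to roughly r² ≈ 0.2 within blocks), MAF uniform on
(0.05, 0.5), 50 causal SNPs (at most one per block) scaled so the genetic
fraction of non-covariate variance is h² = 0.25, phenotype scale
intercept 1.78 and SD 0.58 log10 IU/mL, covariate marginals of an adult
health-checkup cohort (51.4% female, mean age 51.3, 55.8% never-smokers,
57.8% atopic) with scale-matched effects (atopy +0.35, smoking up to
+0.12, male sex +0.12 log10 IU/mL — the study conditions state no
environmental effect sizes, so these are realistic-scale presets), and
0.2% missing calls (MCAR except for targeted artifact samples).

The planted case structure (`asthma_cluster_spec()`) follows the four
published cluster profiles for (genetic burden z, log IgE, onset age,
pFEV1), with mixing proportions from the reported cluster sizes. Two
derived choices deserve note:

* **Within-cluster burden SD = 0.40.** The case cohort's marginal
  IgE_PRS z SD is printed as 0.78 and its mean as ~0.05; with component
  means (1.0, 0.3, −0.4, −0.7) reproducing the published ordering (one
  markedly high-burden cluster, one moderately elevated, two below the
  reference), the between-component variance is ~0.44, forcing a
  within-component SD of √(0.78² − 0.44) ≈ 0.40.
* **`burden_gain = 2` in `simulate_asthma_cohort()`.** The generator
  plants burden on the *true* genetic-value scale by redrawing the causal
  LD blocks from a candidate pool and keeping the draw closest to the
  component target. A measured score explaining R² of the phenotype
  correlates with true burden only at roughly √R² (≈ 0.3–0.5 under the
  defaults), so targets are planted at twice their nominal value to
  appear on the measured-score scale at about the specified separations.

`inject_artifacts()` adds the defects QC must catch: targeted per-sample
missingness, duplicated rows, Mendelian-consistent offspring (transmitted
allele from the parent, the other from the sample allele frequency), and
heterozygosity-inflated samples.

What the generator does **not** emulate: population admixture beyond a
two-subpopulation PCA test pattern, imputation uncertainty, array
intensity artifacts, genotype–environment correlation, and any coupling
between case genotypes and their (component-drawn) log-IgE beyond the
planted burden. Passing tests therefore show algorithmic correctness and
calibration under a clean additive model, not robustness to those
real-data features.

## Numerical choices and degenerate inputs

* GWAS fits with complete dosages share one covariate residualization
  (QR); SNPs with missing dosages are fit per SNP on their complete
  cases. A residual sum of squares below 1e-10 of the total is reported
  at the numerical floor with `degenerate = TRUE`; zero-variance or
  under-determined SNPs give NA rows; collinear covariates are an error
  naming the columns.
* The allelic case-control test is the covariate-free 1-df chi-square on
  the 2×2 allele-count table; the effect is the log allelic odds ratio.
  Monomorphic SNPs give NA rows. No continuity correction anywhere in
  the package — the convention that reproduces published
  contingency-table p-values; note that printed two-significant-figure
  values are sometimes truncated rather than rounded, so recomputations
  are compared at 5% relative tolerance.
* Group tests drop missing values within groups (listwise per group);
  the normality/variance gate routes to "nonparametric" when any group
  has n < 3, when any Shapiro–Wilk p < α, or when the mean-centered
  Levene test (one-way ANOVA on absolute deviations) rejects. With
  three groups at α = 0.05 the gate runs four tests, so even perfectly
  normal data route "parametric" only ~0.95⁴ ≈ 81% of the time — an
  inherent multiplicity property, not a bug.
* Samples scorable by zero model SNPs get NA scores with a warning, are
  excluded from the reference µ/σ, and drop out of clustering with the
  other incomplete rows.
* All randomness flows through explicit seeds (`withr::with_seed`);
  every generator and the whole pipeline are bit-reproducible.

## Problem sizes used by the test and acceptance suites

The suites run on scaled-down instances chosen as representative rather
than exhaustive: LOGO calibration at 1,000–1,500 samples × 2,000 SNPs
(null as a median of 3 runs; signal band over 10 seeds), clustering
recovery at 600–800 cases, the cohort-like preset over 20 seeds, oracle
comparisons on 20-SNP instances and n ≤ 50 enumeration, and one
full-scale end-to-end run (1,287 + 745 × 10,000 SNPs) in the acceptance
script.

## Known limitations

* The leakage property of all-sample scoring, discussed above.
* End-to-end cluster recovery on *measured* scores is weaker than on the
  planted features: the score's measurement noise (SD ≈ 0.85 in
  reference-z units at the default accuracy) is irreducible by the
  generator, so the four-component structure is recovered in only part
  of the runs, with k = 1 otherwise under the conservative homogeneity
  gate. Feature-level recovery (the preset and the 6-SD planted
  partition) is the tested, reliable property.
* Kinship and PCA assume enough independent markers; panels below a few
  thousand SNPs support only first-degree relatedness screening.
* The two-step BIC is a classification-style criterion evaluated along a
  greedy merge path; it is used for k selection only, not as a
  comparable model likelihood.
* No mixed-model association, no shrinkage PRS, no genomic control, no
  X-chromosome handling, no soft cluster assignment.
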