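---
title: "Linking longitudinal brain change across modalities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking longitudinal brain change across modalities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longfuse)
```

## The problem

During adolescence, both the brain's functional organization and its gray
matter anatomy change, and those changes are not independent: subjects whose
functional network connectivity (FNC) reorganizes strongly also tend to show
characteristic patterns of gray matter volume (GMV) change. `longfuse`
implements a pipeline for quantifying that structure-function coupling from
two-timepoint data:

* per subject and timepoint, a 53-network FNC matrix estimated as Pearson
  correlations between post-processed network time courses, and a voxel-wise
  GMV map;
* subject-by-feature *change matrices*, `ΔFNC` (upper-triangle cells) and
  `ΔGMV` (in-mask voxels), defined as **baseline minus follow-up**;
* multivariate decompositions of those change matrices into a small number
  of *change patterns* (sources) and per-subject *loadings*;
* coupling statistics linking the two modalities at the subject level, with
  sex and behavioral-score contrasts.

Two complementary fusion arms are provided. The **asymmetric arm** decomposes
`ΔFNC` alone with infomax ICA, `X = A S`, and then correlates each loading
column of `A` with every voxel of the *raw* `ΔGMV` matrix, yielding
voxel-wise coupling maps. The **symmetric arm** (mCCA + joint ICA) treats the
modalities jointly: `X_k = A_k S_k` for `k ∈ {FNC, GMV}`, where multiset
canonical correlation analysis first finds maximally correlated subject-level
variates across modalities and joint ICA then rotates the linked maps to
spatial independence.

Because the motivating cohort data are access-controlled, the package ships a
first-class synthetic cohort generator with stored ground truth; all
quantitative validation is against planted structure.

## Sign conventions

With `Δ = baseline − follow-up`, a subject who *gains* expression of a
pattern over time has a *negative* loading on it. Consequently a significant
negative one-sample T on a loading column is labelled
`"increase-with-age"` and a positive T `"decrease-with-age"`. This single
convention is applied by `build_delta()`, `loading_tests()` and the
generator, and is asserted in the test suite.

After any ICA, sign and order of components are arbitrary.
`fix_signs_and_order()` canonicalizes: the largest-magnitude element of each
concatenated source row is made positive (one flip shared by all modalities,
so cross-modal loading correlations keep their sign), source rows are scaled
to unit norm with loadings absorbing the scale (so every product `A S` is
unchanged), and components are ordered by explained variance in the FNC
modality. The map is idempotent.

## Time-course post-processing

`postprocess_timecourses()` applies, in order: (1) removal of linear,
quadratic and cubic trends; (2) despiking — samples whose robust z-score
(median/MAD of the detrended series) exceeds 3 are replaced by natural cubic
spline interpolation of the remaining samples; (3) regression of the six
rigid-body motion parameters and their backward first differences; (4) a
zero-phase (forward-backward) 5th-order Butterworth bandpass at
0.01–0.15 Hz. The motion regressors are detrended with the same polynomial
basis as the data before step 3; this makes trend and motion removal commute,
so an input that is exactly a linear combination of motion traces is removed
to numerical zero regardless of step order. Despiking uses a deterministic
rule, keeping the whole pipeline reproducible. At a repetition time of 0.8 s
the filter attenuates a 0.2 Hz oscillation by more than 30 dB (the
forward-backward pass doubles the design attenuation) while passing 0.05 Hz
essentially unchanged.

Mask-based quality control (`qc_masks()`) follows the agreement-correlation
rule: an individual mask is correlated with the >90%-agreement group mask
over the top 10 axial slices, the bottom 10 slices and the whole volume, and
a scan passes at thresholds 0.75 / 0.55 / 0.8 respectively.

## Decomposition choices

**PCA / whitening.** Decompositions operate on row-whitened data
(`pca_model()`): the retained subspace has identity covariance to 1e−8 and
back-projection is the identity on that subspace. Component count defaults to
5 (the count used in the motivating analysis for both modalities); when not
fixed, `select_components_elbow()` picks the point of maximum perpendicular
distance between the normalized eigenvalue curve and its end-to-end chord,
and a flat or perfectly linear spectrum degrades to 1 with a warning.

**Infomax ICA.** `infomax_ica()` maximizes the infomax objective with a
logistic nonlinearity by full-batch natural-gradient ascent,
`W ← W + η (I + (1−2g(WY)) (WY)ᵀ/p) W`, from a seeded random orthogonal
start. Full-batch updates make the fixed point exact and every run
bit-reproducible for a given seed. The learning rate starts at 0.01, grows
gently (×1.02 per accepted step, capped at 0.1) and is annealed ×0.9 with the
step retried whenever an update diverges; convergence is declared when the
largest absolute weight update falls below 1e−6, with a 2048-iteration
budget. The growth schedule matters: at a fixed rate of 0.01 the iteration
contracts so slowly near the optimum that reaching the 1e−6 tolerance takes
roughly 3600 iterations, whereas the capped-growth schedule converges in a
few hundred without affecting the fixed point. All settings are arguments.

**mCCA.** `mcca()` maximizes the SSQCOR objective — the sum of squared
pairwise correlations between same-index canonical variates — stage-wise,
with successive variates orthogonal within each set. Each stage alternates
per-set eigenvector updates inside the orthogonal complement of the previous
stages, initialized from the leading eigenvector of the summed
cross-correlation outer products; for two sets this initialization *is* the
classical CCA solution, so the two-set limit reproduces closed-form CCA to
machine precision (the package's main external oracle). By default the
canonical space is the full numerical rank of each set; the fusion pipeline
passes `reduce = k` so each modality is first cut to a k-dimensional PCA
subspace, which is the variant used for fusion. Reported
`canonical_correlations` are root-mean squared pairwise correlations per
index and are non-increasing by construction. Canonical pairs are
sign-aligned so that same-index variates correlate positively.

**mCCA + jICA.** `mcca_jica()` normalizes each modality (z-score per feature
column, then a global rescale to unit mean square so neither modality
dominates), links them with `mcca(reduce = k)`, concatenates the associated
maps `[C_F | C_G]` and runs infomax ICA on the concatenation, splitting the
joint sources back into `S_F` and `S_G`. Two reporting choices matter and
were made deliberately. First, sources are *estimated* in the normalized
space but *returned* in raw feature units (the per-feature scale is undone
on output): per-voxel z-scoring inflates low-signal blob tails, and
comparing normalized-space sources against raw-unit ground truth caps the
achievable match correlation near 0.88 on the reference simulation, while in
raw units the estimated rank-5 subspace holds the planted sources to about
0.997. Second, the returned loadings are the least-squares fit of the
*uncentered* raw data on those sources, `A_k = X_k S_kᵀ (S_k S_kᵀ)⁻¹`,
rather than the canonical variates carried through the ICA mixing. Canonical
variates are built from column-centered data and therefore have exactly zero
mean, which would make the one-sample loading t-test (the age-direction
inference) identically zero; the least-squares loadings retain a change
shared by all subjects as a nonzero loading mean while leaving every
correlation-based coupling statistic untouched. Each modality then satisfies
its own model `X_k ≈ A_k S_k`, exactly so in the noiseless case.

## Coupling statistics and inference

`voxelwise_coupling()` computes Pearson r between a loading column and every
`ΔGMV` voxel, two-sided p from the t distribution on n−2 degrees of freedom,
and Benjamini–Hochberg FDR across all in-mask voxels (constant voxels are
excluded from the family and reported). The FDR family is per map, not
across components, matching the per-component map presentation of the
analyses the package supports. Significance masks use strict `q <` threshold
comparisons everywhere.

Sex contrasts use the female-minus-male difference of correlations with a
Fisher z two-independent-sample test per element — the asymmetric arm per
voxel (`gender_contrast_asym()`, default FDR level 0.001), the symmetric arm
over the k × k grid of GMV-by-FNC loading pairs (`gender_contrast_sym()`,
FDR across the k² pairs). The 0.001 level is applied to the FDR-adjusted q
by default, with `use_adjusted = FALSE` available where the uncorrected
interpretation is wanted, since the source analyses are ambiguous on this
point. Score contrasts (`quartile_contrast()`, default FDR 0.05) split
subjects at the empirical quartiles (type-7, linear interpolation) with the
lower group defined *inclusively* (scores ≤ Q1, "within or below"), the
upper group as scores ≥ Q3, and report the upper-minus-lower difference of
per-group coupling maps; ties keep all tied subjects, and a degenerate score
distribution (Q1 = Q3) is an error.

Loading-level tests are classical: a one-sample t per loading column
(`one_sample_t()`, `loading_tests()`; BH correction applied jointly across
both modalities and all components), a Welch two-sample t for group
differences (`two_sample_t_by_group()`; Welch because group variances are
not assumed equal), and least-squares site residualization
(`residualize_site()`) as the robustness check for multi-site data —
singleton sites are dropped with a warning and residual site means are
numerically zero.

## The synthetic cohort generator

`simulate_cohort()` generates linked two-modality change data with stored
ground truth. Its defaults are the package's reference conditions: 500
subjects, 53 networks in 7 domains (subcortical 5, auditory 2, sensorimotor
9, visual 9, cognitive control 17, default mode 7, cerebellar 4 — a
configurable default partition), hence 1378 FNC cells; a 12 × 14 × 12 voxel
grid (2016 voxels, full-grid mask by default); k = 5 components; cross-modal
coupling ρ = 0.5 per component; residual noise standard deviation 0.2.

* **FNC sources** are block-structured: each component activates 1–3
  domain-by-domain blocks with a shared random sign per block and magnitudes
  Uniform(0.5, 1), mimicking the modular connectivity-change patterns real
  decompositions produce, and are strongly supergaussian (mostly zero), which
  is what makes them identifiable by ICA. Blocks are sampled without
  replacement across components, so sources have disjoint support and
  pairwise |cos| well under 0.3.
* **GMV sources** are sums of 1–3 isotropic Gaussian blobs (σ ~ U(1.2, 2.5)
  voxels) inside the mask, peak-normalized to 1.
* **Loadings** are bivariate normal per component with unit variances and
  correlation ρ_j + ρ_sex_j for females, ρ_j for males; components are
  independent. This plants both the coupling and its sex difference.
* **Demographics** draw sex with P(F) = 0.478 (the female fraction of the
  motivating cohort's baseline demographic table), baseline age in months as
  round(N(119, 8)) with follow-up exactly 24 months later, and 21 uniform
  site labels.
* **Scores** follow a linear model in the functional loadings plus N(0, 1)
  noise; the default effects (−0.3 on components 4 and 5 for the
  psychopathology change; +0.3 on component 2 and −0.3 on component 5 for the
  cognition change) mirror the component-score association pattern the
  package is designed to detect. The composite scores themselves are
  generated directly — the generator makes no claim about how real composite
  instruments are built.

Everything is a deterministic function of one integer seed; equal seeds give
byte-identical cohorts after serialization.

What the generator does *not* emulate: spatial autocorrelation of
measurement noise, site or scanner effects on the data matrices (sites are
labels only, so site residualization is validated on separately planted
offsets), motion artifacts, non-Gaussian loading distributions, nonlinear
structure-function relationships, and missing-data patterns. Passing the
recovery tests therefore demonstrates correctness of the algorithms under
the stated linear mixed model, not robustness to every property of real
imaging data.

```{r example, eval = FALSE}
cohort <- simulate_cohort(seed = 1)
fit <- fuse_sym(cohort$delta_fnc, cohort$delta_gmv, k = 5, seed = 1)
fit$loading_stats
contrasts <- run_contrasts(sym = fit, sex = cohort$demographics$sex)
contrasts$gender_sym
```

## Validation strategy and problem sizes

The test suite validates every operation against an independent oracle or a
planted truth: closed-form CCA for the two-set mCCA limit; the Amari index
for infomax separations of sparse supergaussian mixtures; greedy
source-matching correlations on synthetic cohorts (20 seeds at the reference
conditions; median matched |r| ≈ 0.99 in both modalities); Fisher-z
confidence intervals for planted coupling and its sex offset (n = 2000 per
group); a brute-force step-up rule for BH-FDR (exact agreement on 1000
random vectors); 100-replicate global-null simulations for empirical FDR
(200 subjects × 2000 voxels); 20-seed sign checks for the quartile contrast
(200 subjects × 600 voxels); and filter-response measurements for the
bandpass. These sizes were chosen so that the statistical checks have clear
margins while the whole suite runs in about a minute; `scripts/acceptance.R`
re-runs the same computations from scratch and writes the resulting numbers
as JSON.

## Known limitations

* Single ICA run per seed; no ICASSO-style multi-run cluster stability
  (multi-seed comparison is easy to script, but not built in).
* The mCCA variant is SSQCOR with stage-wise deflation; other multiset
  objectives (MAXVAR, GENVAR) are not implemented, and no claim is made of
  numerical equivalence to any particular toolbox implementation beyond the
  two-set CCA limit.
* Only two-modality fusion is exercised end-to-end, although `mcca()`
  accepts any number of sets.
* Spatial inference is voxel-wise FDR only — no cluster-extent or
  permutation-based spatial statistics, and no anatomical labelling.
* Raw-image preprocessing (registration, distortion correction,
  segmentation, spatial ICA network estimation) is upstream of this package;
  inputs are network time courses / FNC matrices and GMV maps.
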