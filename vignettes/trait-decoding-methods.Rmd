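---
title: "Decoding autistic traits from emotion-evoked fMRI patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding autistic traits from emotion-evoked fMRI patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`traitscan` implements a complete, simulation-backed analysis chain linking a
continuous autistic-trait score — the 50-item Autism Spectrum Quotient (ASQ),
total range 0–50 — to multivoxel fMRI responses evoked by emotional faces,
with a genotype-moderated functional-connectivity stage. Because raw
individual-level fMRI of this kind is generally not shareable, the package
ships a synthetic cohort generator with known ground truth; every downstream
stage is validated against what was injected. This vignette describes each
model, the tunable parameters and their defaults, the numerical choices, and
what the synthetic validation does and does not establish about real data.

## The synthetic cohort generator

`cohort_spec()` + `simulate_cohort()` define a cohort; `simulate_subject_bold()`
materializes one subject's runs so large cohorts never sit in memory at once.
The emulated design is an event-related implicit emotion-recognition task: 50
grayscale face stimuli (10 each of angry, fear, happy, neutral, sad) presented
once per run in a pseudorandom order, two runs of 173 volumes at TR = 2 s,
inter-trial intervals jittered uniformly on 2–6 s, first onset at 10 s. The
run-length check requires the realized schedule plus the full 32-s HRF support
to fit inside the run.

**ASQ scores.** Item responses follow a two-parameter logistic item-response
model on a standard-normal latent trait with a common discrimination and a
spread of item difficulties. The two free parameters are calibrated once, by
Gaussian quadrature (no simulation), so the marginal total-score distribution
matches the target mean 21.4 and SD 5.6; totals are the item sums by
construction.

**Genotypes.** Four OXTR SNPs (rs2254298, rs2268491, rs2268498, rs53576) are
drawn independently at Hardy–Weinberg proportions \(p^2, 2pq, q^2\); the
carrier flag implements the dominant A+/T+ grouping (at least one risk
allele). Default risk-allele frequencies (0.30, 0.25, 0.45, 0.60) are chosen
to be plausible for an East-Asian cohort; for rs2254298 this yields a
near-balanced carrier split (~51% A+), which is what makes a two-group
moderation analysis well-posed at desk scale. Linkage disequilibrium between
SNPs is deliberately not modelled.

**BOLD.** Every in-mask voxel responds to all five conditions with unit
amplitude on a baseline of 100, through the canonical double-gamma HRF.
Three kinds of structure are injected on top:

* *Trait-encoding pattern*: inside `pattern_region`, the (angry − neutral)
  amplitude of voxel \(v\) for subject \(i\) is
  \(w_v\,(s\,z_i + u_i) + \varepsilon_{vi}\), where \(z_i\) is the
  standardized trait, \(s\) is `pattern_strength`, \(w_v \sim N(1, 0.2)\) are
  stored pattern weights, \(u_i \sim N(0, \sigma_u)\) is a trait-independent
  subject-level reactivity factor (`subject_amp_sd`), and
  \(\varepsilon_{vi} \sim N(0, \sigma_a)\) is voxel-level amplitude noise
  (`amp_noise_sd`).
* *Condition-specific coupling*: seed-region voxels follow a shared neural
  series whose per-event amplitudes are jittered (`trial_gain_sd`); target
  voxels additionally receive gain × (seed series restricted to condition c),
  with the angry-condition gain
  \(\beta_0 + \text{slope}(\text{carrier group})\times z_i\) and all other
  condition gains zero. The trial-wise jitter is what makes the
  psychophysiological interaction identifiable over and above the
  psychological regressor.
* *Nuisance*: slow random-walk motion series (six columns) enter the signal
  through small subject-specific coefficients, and i.i.d. Gaussian scan noise
  of SD `noise_sd` is added last, so noiseless cohorts are bit-reproducible
  prefixes of noisy ones.

Scan noise is white by design (the real acquisition's autocorrelation is
unknowable and white noise keeps the GLM oracles exact); there is no head
motion displacement, slice timing, physiological noise, spatial smoothness,
or k-space physics. The grid is a desk-scale stand-in for MNI space
(default 20³ voxels at 3 mm, ellipsoidal grey-matter mask; the validation
experiments use 16³), with a diagonal RAS affine.

`calibrate_pattern_strength()` inverts the generator's closed-form signal
model,
\(r = s\bar w / \sqrt{s^2 \bar w^2 + \sigma_u^2 \bar w^2 + (\sigma_a^2 + \sigma_g^2)/m}\),
where \(\sigma_g\) is the GLM contrast noise implied by the design efficiency
and \(m\) the region size, to choose \(s\) for a target correlation between
the trait and the region-mean (angry − neutral) contrast.

## First-level GLM

`build_design_matrix()` assembles, per run, five HRF-convolved condition
regressors (events as 0-duration impulses by default; convolution on a
16×-oversampled grid before sampling at scan times), six motion columns
appended verbatim, and a run intercept; runs are fitted jointly as a block
design (5 + 6 + 1 = 12 columns per run). `fit_glm()` is voxelwise OLS via a
single QR decomposition; `contrast_map()` applies per-regressor weights, with
`contrast_weights()` averaging the named condition across runs
(+1/runs, −1/runs). No temporal filtering or prewhitening is applied by
default because the synthetic noise is white; per-run fitting is available by
subsetting the event table.

## Searchlight SVR decoding

For every in-mask centre, the features are the in-mask voxels of the
surrounding sphere (radius 3 voxels by default, 123 lattice offsets;
`min_voxels = 10` to attempt a fit), and each subject's ASQ total is
predicted by a linear epsilon-insensitive SVR (C = 1, epsilon = 0.1, the
libsvm implementation via e1071) under a single balanced 10-fold
cross-validation partition shared by all centres (for n = 229 that is folds
of 22 or 23). The centre's reported statistic `r` is the Pearson correlation
between the pooled out-of-fold predictions and the observed scores — the
prediction-outcome correlation. No feature standardization is applied by
default (z-scoring within training folds is available).

Two numerical points deserve emphasis, because both were measured during
development and both matter for inference:

1. **Fold-mean centring.** Pooled out-of-fold predictions carry a spurious
   *negative* correlation with the outcome: each fold is predicted by a model
   whose training mean excludes exactly that fold, so fold-level prediction
   offsets anti-track fold-level outcome means (measured bias of the null
   pooled r: about −0.10 at n = 60, k = 10). The default therefore removes
   each fold's mean prediction before pooling (`center_folds = TRUE`), which
   removes the bias without touching the within-fold ordering.

2. **Null variance inflation.** Even after centring, the pooled r is not
   t-distributed under the null: predictions depend on every other subject's
   outcome through training, inflating the null SD of r from the nominal
   \(1/\sqrt{n-1}\) ≈ 0.13 to about 0.17 at n = 60 regardless of feature
   scale. A two-sided t transform with n − 2 df is therefore anticonservative
   (measured false-positive rate 0.12–0.15 at alpha = 0.05). The default p
   (`p_method = "fold_t"`) instead combines the per-fold prediction-outcome
   correlations with the variance-corrected resampled t-test — the
   Nadeau–Bengio standard-error inflation \(\sqrt{1/k + n_{te}/n_{tr}}\) with
   k − 1 df — which restores the nominal null rate (measured 0.04–0.05).
   The plain t transform remains available as `p_method = "t"`, and
   label-permutation p-values as `p_method = "permutation"` (exact but slower
   by a factor `n_perm`).

The p map is thresholded by Benjamini–Hochberg FDR within the mask at
`fdr_q = 0.0125` — the family budget of 0.05 split over the four
emotion > neutral contrast maps (`per_map_q()`), two-sided. Spheres are
truncated at the mask boundary; the radius is interpreted in voxel units.
Shrinking the radius to 0 reduces the analysis to univariate per-voxel SVR,
an internal consistency check in the test suite.

## Generalized PPI

`extract_seed_timeseries()` averages the in-mask voxels whose mm centres lie
within the seed sphere (6-mm radius by convention; 33 voxels on a 3-mm grid).
`deconvolve_neural()` inverts the HRF convolution operator at scan resolution
with a ridge penalty (`ridge_lambda = 1e-2` by default; the reconvolution
residual stays below 10% on noiseless inputs across the documented 1e-3–1e-1
range). Deconvolution is performed at scan resolution deliberately: the data
contain no information about sub-TR structure, and a full oversampled-grid
inversion would be a ~5500² solve per run for no estimation benefit. The PPI
product is nevertheless formed at the oversampled grid: the neural estimate
is step-upsampled, multiplied by the condition's event indicator there,
reconvolved with the HRF and sampled at scan times — one PPI column per
condition (the generalized form), alongside the five psychological columns,
the observed (mean-centred) seed series as the physiological column, motion,
and run intercepts. `ppi_coupling_map()` fits this design voxelwise by OLS
and returns the angry-PPI minus neutral-PPI beta, the only contrast with
genotype effects in the emulated study; other pairs are available through
`contrast_weights()`. The ridge deconvolution replaces the empirical-Bayes
deconvolution of the original gPPI toolbox — same role, simpler contract —
so equivalence to that toolbox is approximate by design.

## Group genotype × trait inference

`build_interaction_design()` codes carrier status ±½ and mean-centres the
trait before forming the product, so the main effects remain interpretable
and the product column is not collinear with the trait. The interaction t
map (df = n − 4) is corrected by Freedman–Lane permutation of reduced-model
residuals with the max-|t| statistic over the mask (`n_perm = 1000` by
default, +1 smoothing, so the smallest attainable corrected p is
1/(n_perm+1)). Permutation FWE replaces random-field-theory peak correction,
whose smoothness estimation is meaningless on desk-scale unsmoothed grids.
Suprathreshold voxels (peak p_FWE < 0.05) are labelled by 18-connectivity
(faces + edges) connected components, components with extent ≤ 10 are
discarded (`k > 10`), and peak p-values are Bonferroni-corrected ×3 for the
emotion family. For each surviving cluster, per-subject mean coupling is
extracted and per-group Pearson correlations with the trait are reported with
Bonferroni ×8 (4 SNPs × 2 allele groupings) and a sign-opposition flag. All
tests are two-sided; a one-tailed report (halving the two-sided p) exists
only as an explicit option, never silently.

## Shared statistics

Hardy–Weinberg equilibrium is tested by the conventional 1-df chi-square
against \(\hat p^2, 2\hat p\hat q, \hat q^2\) (an exact test is out of
scope). The repeated-measures ANOVA is the one-way within-subject
decomposition with df \((c-1, (c-1)(n-1))\) — no sphericity correction,
matching the emulated report style — and partial eta squared
\(SS_{cond}/(SS_{cond}+SS_{err})\); post-hoc pairwise paired t-tests are
Bonferroni-corrected by the number of pairs. The sample-size justification is
reproduced analytically: `min_power()` returns the minimum of the
Pearson-correlation power (Fisher-z approximation, medium effect r = 0.3,
full sample) and the independent-samples t power (noncentral t, medium
effect d = 0.5, the 131/124 demographic split), the two declared test
families; "medium" follows Cohen's conventions.

## Validation experiments and their scales

Three frozen cohort presets on a 16³ grid at 3 mm define the validation
conditions (all n = 60):

* `null_cohort_spec()` — no injected signal, spherical mask of 257 voxels.
  Used for: the voxelwise false-positive rate of the searchlight test at
  alpha = 0.05 over 50 cohorts, and the rate at which BH at q = 0.0125 flags
  anything (at most q of null cohorts, up to Monte-Carlo error). The
  permutation-FWE null calibration (200 cohorts × 500 permutations in the
  test suite) simulates the group stage directly — Gaussian null coupling
  maps with real phenotype draws — because the statistic under test only
  sees the coupling maps, and 200 full BOLD-to-gPPI pipelines would add
  hours for no additional coverage.
* `pattern_cohort_spec()` — 123-voxel pattern ball in a 912-voxel mask,
  scan noise 0.5, subject-amplitude SD 0.02, voxel amplitude noise 0.05,
  calibration target 0.9 for the region-mean amplitude correlation. The
  stringent combination of a null-calibrated fold-level test, n = 60, and
  q = 0.0125 means a moderate effect cannot reach the BH cascade at all; the
  recovery experiment therefore injects a strong calibrated effect — the
  cross-validated decoder r inside the region comes out around 0.7 — and
  asks whether the FDR-surviving set overlaps the injected region
  (Dice > 0.3; measured 0.4–0.6 across pilot seeds).
* `coupling_cohort_spec()` — 33-voxel seed and target balls in a 624-voxel
  mask, trial-gain jitter SD 1.0, angry-condition coupling slopes ∓0.8 per
  trait SD by rs2254298 carrier group around a base gain of 0.3, scan noise
  1.0. Used for: per-subject gain-sign recovery through the full gPPI chain
  (Spearman-scale correlation with injected gains > 0.5) and full-pipeline
  interaction recovery — a surviving cluster overlapping the target region
  with opposite per-group slope signs — across 20 seeds.

These scales were chosen so the whole suite runs on one CPU in tens of
minutes; `scripts/acceptance.R` re-runs the same experiments at reduced
replicate counts (15 null cohorts, 100 FWER cohorts × 300 permutations, 10
interaction seeds) and writes every quantity it computes as JSON.

**What passing does and does not show.** The synthetic validation
establishes that the implementation is correct and calibrated under its own
generative model: white noise, a single compact pattern region, linear
trait-amplitude coupling, HWE genotypes, no motion, no spatial
autocorrelation. It does not establish sensitivity under realistic fMRI
noise spectra, spatially extended or distributed codes, or confounded
designs, and the injected effect sizes needed for reliable detection at
n = 60 are larger than what real cohorts of this size would plausibly carry
— the emulated study used n = 229 for good reason.

## Known limitations

* AR(1) scan noise and prewhitening are not implemented; the white-noise
  default makes the no-prewhitening GLM exactly efficient.
* The searchlight's fold-level default p trades power for calibration; with
  hundreds of subjects the plain pooled-r t transform becomes much less
  biased and `p_method = "t"` may be preferred for comparability.
* Cluster tables carry no anatomical labels (the Region column is blank;
  synthetic runs can be annotated from ground-truth region names).
* The behavior simulator models accuracy as binomial proportions and RT as
  log-normal medians per condition — enough to exercise the RM-ANOVA and
  correlation stages, not a cognitive model.
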