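# traitscan

Searchlight decoding of autistic traits from task fMRI, with
genotype-moderated functional connectivity — as a tested, simulation-backed
R pipeline.

## The problem

Autistic traits vary continuously in the general population (the 50-item
Autism Spectrum Quotient, ASQ, totals 0–50). A dimensional neuroimaging
analysis asks: do local multivoxel patterns of brain responses to emotional
faces *predict* an individual's ASQ score, and is the functional coupling
between the identified regions moderated by oxytocin-receptor (OXTR)
genotype? `traitscan` implements that full analysis chain for researchers
who want to run it, extend it, or validate it without access to raw fMRI:

1. **Synthetic cohort generator** — an event-related implicit
   emotion-recognition design (5 face conditions × 10 stimuli × 2 runs of
   173 volumes, TR 2 s), ASQ scores from a calibrated item-response model
   (mean ≈ 21.4, SD ≈ 5.6), four OXTR SNPs at Hardy–Weinberg equilibrium
   with dominant carrier grouping, and BOLD volumes with known injected
   ground truth: a trait-encoding (angry − neutral) pattern region and
   condition-specific seed→target coupling whose trait slope differs in
   sign by genotype group.
2. **First-level GLM** — canonical double-gamma HRF, per-run condition +
   motion + intercept design, voxelwise OLS, emotion > neutral contrast
   maps.
3. **Searchlight MVPA** — 3-voxel-radius spheres, linear support vector
   regression (C = 1) under shared 10-fold cross-validation; each centre is
   scored by the prediction-outcome correlation
   r = cor(predicted ASQ, actual ASQ), thresholded by Benjamini–Hochberg
   FDR at q = 0.05/4 = 0.0125 (two-sided, family of four contrasts).
4. **Generalized PPI** — 6-mm seed spheres, ridge deconvolution to the
   neural level, one seed×condition interaction regressor per condition,
   per-subject angry-vs-neutral coupling contrast maps.
5. **Group genotype × trait inference** — carrier (±½) × mean-centred-trait
   interaction GLM, permutation max-|t| family-wise error correction,
   cluster extent k > 10, Bonferroni ×3 (emotions) and ×8 (SNPs × alleles),
   per-group trait–coupling slopes with sign-opposition reporting.
6. **Shared statistics** — Hardy–Weinberg chi-square, Pearson tests,
   repeated-measures ANOVA with partial eta squared, Bonferroni, and the
   analytic power computations behind the "N = 255 gives >90% power for
   medium effects" sample-size claim.

Everything is tibble-first: results come back as tibbles or carry
broom-style `tidy()`/`glance()` methods, and `autoplot()`/`plot_*()` give
ggplot2 figures.

## Worked example

Simulate a 40-subject cohort in which the angry-condition coupling between
a seed and a target region has slope +0.8 per trait SD in rs2254298
non-carriers and −0.8 in carriers, run the per-subject gPPI chain, and test
the group interaction:

```r
library(traitscan)

spec   <- coupling_cohort_spec(n_subjects = 40, seed = 9)
cohort <- simulate_cohort(spec)

coupling <- fit_gppi(cohort)                      # subjects x voxels
fit <- group_interaction(coupling, cohort$phenotypes,
                         snp = "rs2254298", n_perm = 500, seed = 1)
fit
#> <group_interaction> SNP rs2254298: 1 surviving cluster(s) at peak p_FWE < 0.05, k > 10
#> # A tibble: 1 × 11
#>   cluster     k peak_i peak_j peak_k     x     y     z peak_stat   p_fwe
#>     <int> <int>  <int>  <int>  <int> <dbl> <dbl> <dbl>     <dbl>   <dbl>
#> 1       1    33     12      9      8  10.5   1.5  -1.5     -15.4 0.00200
#> # ℹ 1 more variable: p_corrected <dbl>

fit$reports[[1]]
#> # A tibble: 2 × 6
#>   group          n      r        p p_corrected slope_sign
#>   <chr>      <int>  <dbl>    <dbl>       <dbl>      <dbl>
#> 1 noncarrier    20  0.975 3.81e-13    3.05e-12          1
#> 2 carrier       20 -0.976 2.60e-13    2.08e-12         -1
```

One cluster survives peak-level permutation FWE (p_FWE = 0.002, ×3
Bonferroni p = 0.006): its 33 voxels are exactly the injected target
region, the peak interaction t is −15.4, and the extracted coupling
correlates with ASQ *positively* in non-carriers (r = 0.98) and
*negatively* in carriers (r = −0.98) — the injected sign-opposite
moderation, recovered end-to-end. (The synthetic effect is deliberately
strong; see the methods vignette for what the preset injects.)

Decoding works the same way: `fit_first_level()` turns a cohort into
angry > neutral contrast maps, `searchlight_predict()` returns the
per-voxel prediction-outcome r with FDR flags, and `glance()` summarizes:

```r
spec   <- pattern_cohort_spec(n_subjects = 60, seed = 1)
cohort <- simulate_cohort(spec)
maps   <- fit_first_level(cohort)
pm     <- searchlight_predict(maps, cohort$phenotypes$asq_total)
glance(pm)
#> # A tibble: 1 × 10
#>   contrast     n_subjects n_voxels n_tested radius_vox n_folds  fdr_q critical_p
#>   <chr>             <int>    <int>    <int>      <dbl>   <int>  <dbl>      <dbl>
#> 1 angry>neutr…         60      912      912          3      10 0.0125    0.00649
#> # ℹ 2 more variables: n_significant <int>, peak_r <dbl>
```

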