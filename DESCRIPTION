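Package: traitscan
Title: Searchlight Decoding of Autistic Traits from Task fMRI with
    Genotype-Moderated Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, simulation-backed pipeline for linking a
    continuous autistic-trait score (Autism Spectrum Quotient, ASQ) to
    multivoxel fMRI response patterns. Provides a synthetic event-related
    fMRI cohort generator with known ground truth (item-response ASQ
    scores, Hardy-Weinberg genotypes, event schedules, BOLD volumes with
    injected trait-encoding patterns and condition-specific seed-target
    coupling); first-level GLM fitting with a canonical double-gamma HRF;
    spherical-searchlight support-vector-regression decoding of the trait
    from emotion-contrast beta maps with cross-validated
    prediction-outcome correlation and Benjamini-Hochberg FDR
    thresholding; generalized psychophysiological interaction (gPPI)
    seed-to-voxel coupling maps via ridge deconvolution; group-level
    genotype-by-trait interaction inference with permutation max-t
    family-wise error control, cluster-extent filtering, and per-group
    slope reports; plus shared statistical utilities (Hardy-Weinberg
    test, repeated-measures ANOVA with partial eta squared, Bonferroni
    correction, and analytic power computations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
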