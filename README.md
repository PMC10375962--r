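# kidneyls

Two-phase kidney segmentation for dynamic contrast-enhanced (DCE) MRI
slices, for image-analysis researchers who have a pixel-wise
kidney-probability source (a CNN or any other classifier) and want its
output refined into an anatomically coherent mask.

Pixel-wise classifiers learn intensity well but shape poorly: their masks
carry false-positive islands in the background and false-negative holes
inside the kidney, especially in the low-contrast pre-enhancement frames.
`kidneyls` refines such output with a level-set contour — the zero level of
a field φ, positive inside the kidney — evolved to minimize

    E(φ) = λ₁ Σ δ_ε(φ) |∇φ|
         + λ₂ Σ [ V_ε(φ) U_B P_B + (1 − V_ε(φ)) U_K P_K ]

where `V_ε`, `δ_ε` are the sine-regularized Heaviside step and its
derivative, `U_K` (with `U_B = 1 − U_K`) is the phase-one probability map,
and `P_K`, `P_B` is a Bayesian probabilistic shape prior built from
co-registered expert masks with pseudo-count smoothing
(`P_L = [(N_L + β)/(N + βO)]·[N/(N + l − O)]` for observed labels), so the
prior never saturates to 0 or 1. The gradient-descent update is

    φ ← φ + τ δ_ε(φ) [ λ₁ div(∇φ/|∇φ|) + λ₂ (U_K P_K − U_B P_B) ]

with the fixed working parameters λ₁ = λ₂ = 6, ε = 1.5, τ = 0.8, β = 1.
The package contains everything needed to exercise this end-to-end without
clinical data: raster I/O (PNG/TIFF/NIfTI), a DCE phantom generator with
gamma-variate enhancement and CNN-style probability-map corruption, affine
registration and prior construction, the level-set engine, Dice / IoU /
95th-percentile Hausdorff evaluation, and an optional natively trained
convolutional provider. See the methods vignette
(`vignettes/methods.Rmd`) for the full model and the numerical choices.

## Worked example

Build a shape prior from a co-aligned phantom cohort, corrupt a held-out
subject's probability map with three false-positive blobs and two holes,
and refine:

```r
library(kidneyls)

base <- phantom_config(image_size = c(128, 128), n_frames = 4,
                       semi_axes = c(32, 17), t0 = 1, beta_t = 1.5,
                       noise_var = 0.01, seed = 1)
vb <- cohort_variability("aligned"); vb$semi_axes <- 2
prior_cohort <- make_cohort(12, base, vb, seed = 11)
prior <- build_prior_from_cohort(prior_cohort, beta = 1, register = FALSE)
prior
#> <shape_prior 128 x 128 from N = 12 masks, beta = 1, P_K in [0.0769, 0.9231]>

subject <- make_cohort(2, base, vb, seed = 99)[[1]]
cc <- corruption_config(n_fp_blobs = 3, fp_blob_radius = c(4, 7),
                        n_fn_holes = 2, fn_hole_radius = c(2, 4),
                        boundary_blur_sigma = 1, seed = 5)
u <- corrupt_probability_map(subject$truth, cc)

baseline <- label_mask((u$p_kidney > 0.5) * 1L)
dice(baseline, subject$truth); hd95(baseline, subject$truth)
#> baseline (threshold 0.5): Dice 0.913, HD95 35.8 px

res <- segment_ls(subject$frames[[3]], u, prior,
                  init = list(shape = "circle", center = c(20, 20), radius = 10))
res
#> <ls_result: 1653 kidney pixels, 25 iterations, converged = TRUE>
dice(res$mask, subject$truth); hd95(res$mask, subject$truth)
#> refined: Dice 0.980, HD95 1.4 px
```

Thresholding the corrupted map alone scores Dice 0.913 with a 35.8 px HD95
(the blobs dominate the Hausdorff distance); the prior-guided contour
removes every planted false positive, fills the holes, and reaches
Dice 0.980 / HD95 1.4 px from an initialization far from the kidney.
`autoplot(res)` shows the energy descent; `run_pipeline()` /
`run_baseline_threshold()` orchestrate whole cohorts including affine
alignment to the prior's reference frame, and `inst/cli/kidneyls.R` exposes
the same steps as shell verbs (`phantom`, `prior`, `probmap`, `segment`,
`evaluate`).

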