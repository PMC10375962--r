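---
title: "Prior-guided level-set kidney segmentation: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-guided level-set kidney segmentation: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kidneyls)
```

## The problem and the two-phase model

Dynamic contrast-enhanced (DCE) MRI of the kidney produces a time series of
scans whose tissue intensities change as the contrast agent passes through:
early frames show little kidney/background contrast, frames around the
first-pass peak show strong enhancement. Renal function assessment needs the
kidney segmented in each frame, which is hard exactly where it matters — in
the low-contrast frames — and pixel-wise classifiers (CNNs included) learn
intensity well but shape poorly, producing false-positive islands in the
background and false-negative holes inside the organ.

`kidneyls` implements a two-phase remedy. Phase one produces a per-pixel
kidney probability map $U_K(x,y) \in [0,1]$ (with $U_B = 1 - U_K$) from any
provider: a CNN, a simple two-class Gaussian intensity model, or a
truth-derived oracle with controllable corruption for studies. Phase two
refines it with a level-set contour $\Gamma_c$, the zero level of a field
$\phi(x,y)$ that is positive inside the kidney and negative outside,
evolved to minimize

$$E(\phi) = \lambda_1 \sum_{x,y} \delta_\varepsilon(\phi)\,|\nabla\phi|
 \;+\; \lambda_2 \sum_{x,y} \Big[ V_\varepsilon(\phi)\, U_B P_B +
 (1 - V_\varepsilon(\phi))\, U_K P_K \Big],$$

where $V_\varepsilon$ and $\delta_\varepsilon$ are the sine-regularized
Heaviside step and its derivative (compactly supported on
$|\phi| \le \varepsilon$), and $P_K, P_B$ are the probabilistic shape prior
described below. The first term shortens the contour; the second moves it
toward pixels where the combined probability-map and prior evidence favours
kidney. Gradient descent gives the explicit update

$$\phi \leftarrow \phi + \tau\, \delta_\varepsilon(\phi)
 \Big[ \lambda_1\, \mathrm{div}\!\left(\tfrac{\nabla\phi}{|\nabla\phi|}\right)
 + \lambda_2 (U_K P_K - U_B P_B) \Big].$$

Because $\delta_\varepsilon$ vanishes outside the band
$|\phi| \le \varepsilon$, only band pixels ever move (`evolve_step()` leaves
the rest bit-identical). The data force at each pixel is constant over the
run, so the evolution is a monotone relaxation wherever one label's evidence
dominates; the curvature term arbitrates at the boundary.

## The Bayesian shape prior

The prior is built from $N \ge 2$ expert masks co-registered to a reference
image. At a pixel where the kidney was seen in $N_K$ of the $N$ masks, with
$O$ the number of labels observed there ($O = 2$ when $0 < N_K < N$, else
$O = 1$), $l = 2$ labels, and pseudo-count $\beta > 0$, an observed label $L$
receives

$$P_L = \frac{N_L + \beta}{N + \beta O}\cdot\frac{N}{N + l - O},$$

and an unobserved label receives $\frac{1}{l - O}\left(1 - \frac{N}{N + l - O}\right)$.
For $O = 2$ and $\beta = 1$ this reduces to Laplace smoothing
$(N_K + 1)/(N + 2)$; for a pixel seen as kidney in all $N$ masks it gives
$N/(N+1)$ for kidney and $1/(N+1)$ for background. The point of the
construction is that probabilities are never exactly 0 or 1 — a raw
occurrence-frequency prior would veto any pixel outside the training union
outright, whereas the smoothed prior merely penalizes it, leaving the
probability map able to overrule a weak prior. The second factor
$N/(N+l-O)$ equals 1 whenever $O = 2$; it is kept literally for generality
to more than two labels. `build_shape_prior()` is verified in the test suite
against an independent scalar evaluation of these formulas over exhaustive
count tables ($N = 2..6$, all $N_K$, several $\beta$).

Registration to the reference uses normalized cross-correlation over the six
affine coefficients, a three-level block-mean pyramid, and a
centroid-plus-second-moment initialization (`register_affine()`); the
returned transform never scores below its initialization. Masks are
resampled by nearest neighbour to preserve binarity. Segmentation happens in
the prior's reference space and the mask is mapped back to native space with
the inverse transform; the alternative (warping the prior into native space)
would be a straightforward config extension but is not implemented.

## Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| $\lambda_1$ | length-term weight | 6 | fixed working value |
| $\lambda_2$ | data-term weight | 6 | fixed working value |
| $\varepsilon$ | Heaviside/Dirac band half-width (px) | 1.5 | also the update band |
| $\tau$ | time step | 0.8 | adaptively halved near stalls (below) |
| $\beta$ | prior pseudo-count | 1 | Laplace smoothing |
| `max_iters` | iteration cap | 1000 | runs typically converge in 25–100 |
| `conv_tol_frac`, `conv_window` | stopping rule | $10^{-4}$, 10 | see below |

The stopping rule declares convergence when the number of pixels whose label
(sign of $\phi$) changed stays below 0.01% of the image for 10 consecutive
iterations.

## Numerical choices

**Bounded initialization.** `init_phi()` builds $\phi$ as a signed distance
(analytic for circles/rectangles, Euclidean distance transform for seed
masks), but a raw signed distance leaves every pixel farther than
$\varepsilon$ from the initial contour frozen forever, since
$\delta_\varepsilon = 0$ there — a far-off initialization could then never
reach the kidney. `segment_ls()` therefore clamps the initial field to
$\pm\min(1,\, 0.95\varepsilon)$, preserving the zero level while placing
every pixel inside the active band. This is the binary-level-set practice
that makes the result independent of where the contour starts, and it is
what the initialization-invariance tests exercise.

**Step limiting.** A single explicit step can move a band pixel across the
band boundary when a transient curvature spike coincides with a large data
force; the pixel would then freeze outside the band, stranding one-pixel
islands. Updates are therefore capped at $\varepsilon/5$ per iteration, so
leaving the band requires a sustained, not momentary, force.

**Adaptive damping.** A fixed explicit step can settle into a period-2
oscillation at force-balance pixels (energy bouncing between two values).
When the energy fails to descend relative to two iterations earlier while
label changes are already small, the internal step is halved (floor
$\tau/64$). The oscillation amplitude scales with the step, so the flip-flop
dies out and the label-change criterion can fire.

**Curvature.** Central differences with replicate (Neumann) boundaries;
the gradient magnitude is safeguarded as $\sqrt{|\nabla\phi|^2 + \eta^2}$
with $\eta = 10^{-8}$, so flat fields give zero rather than NaN. On a
signed-distance disk of radius $r$ the discrete operator reproduces $-1/r$
near the zero level within 5%.

**No re-initialization.** $\phi$ is not periodically reset to a signed
distance; the compact-support Dirac keeps updates confined and the runs
converge without it. A `reinit_every` flag exists for robustness studies.

**Quadrature.** Energy sums are plain pixel sums (unit grid spacing inside
the solver); physical spacing enters only in the evaluation metrics.

## The phantom generator

Real per-patient data (tens of 256×256 scans with expert masks) are not
shippable, so the `phantom` module generates the study material: a
bean-shaped kidney (rotated ellipse with a medial notch) whose mean
intensity follows a gamma-variate first-pass enhancement curve
$g(t) \propto ((t-t_0)\beta_t/\alpha)^\alpha e^{\alpha(1 - (t-t_0)\beta_t/\alpha)}$
(zero before arrival $t_0$, unit peak at $t_0 + \alpha/\beta_t$), two static
non-kidney structures and a body outline anchored to the kidney's pose (so
scene-level affine registration is meaningful), and additive zero-mean
Gaussian noise on the $[0,1]$ intensity scale at the canonical variances
0.01/0.02/0.05. Early frames therefore have a strictly lower
contrast-to-noise ratio than the peak frame, mimicking the hard low-contrast
regime.

`corrupt_probability_map()` turns a truth mask into a CNN-like probability
map: false-positive disks planted in the background (disjoint from the
kidney dilated by 3 px, from each other, and from any caller-supplied
`avoid` region such as the prior support), false-negative disks inside the
kidney, uniform label noise, and Gaussian boundary blur. Planted blobs carry
probability 0.9 and holes 0.1 by default — confident but unsaturated errors,
as sigmoid outputs rarely hit exactly 0 or 1.

Cohorts jitter geometry and enhancement per subject. Two variability
profiles are provided (`cohort_variability()`): `"native"` includes pose
(translation/rotation), for pipelines that perform registration; `"aligned"`
keeps only what affine registration cannot remove (semi-axes, notch,
enhancement timing, a 1 px pose residual), for engine-level studies on
co-registered cohorts. The aligned defaults give pairwise truth-mask Dice of
roughly 0.8–0.97 across subjects, matching what one expects of affinely
co-registered kidneys. Study sizes used by the tests and the acceptance
script — a 30-subject prior cohort, 20 corrupted test cases, 10 clean
recovery cases at 256×256, registration recovery at 128×128 — were chosen as
the smallest cohorts at which the cohort statistics are stable.

What the phantom does *not* emulate: Rician noise statistics, k-space or
coil artifacts, respiratory motion, neighbouring organs with kidney-like
enhancement, or multi-organ anatomies. Passing phantom tests therefore
demonstrates the correctness of the machinery — formulas, registration,
evolution, convergence, the prior's false-component suppression — not
clinical-grade accuracy on real DCE-MRI.

## The CNN provider

The optional phase-one CNN (`cnn_config()`, `build_model()`,
`train_provider()`) is a compact U-style encoder–decoder: paired 3×3
convolutions with ReLU and dropout per level, 2×2 max-pooling, up-convolution
with skip concatenation, and a final 1×1 convolution with sigmoid output, so
$U_B = 1-U_K$ holds structurally. Training is implemented natively (im2col
convolutions on BLAS, manual backpropagation, Adam, binary cross-entropy,
optionally plus soft-Dice) with the canonical recipe: initial learning rate
$10^{-4}$ (toy runs use larger), dropout 0.5, decay by 10% after 10 epochs
without validation improvement. `augment_pair()` produces exactly 12
variants per training pair — 1 random translation, rotations of ±45°, ±90°,
180°, two flips, three noise levels, and a combined translation+flip; the
split of the twelve across operation families is this package's choice and
is configurable. The `bcd_unt` variant (dense convolutions in the deepest
encoder block, recurrent skip fusion) is available as an inspectable
architecture description; its training is out of scope, and the level-set
phase depends only on the probability-map contract in any case.

## Evaluation metrics

Dice $2|A\cap B|/(|A|+|B|)$ and IoU $|A\cap B|/|A\cup B|$ (both defined as 1
for two empty masks), and HD95: boundary pixels are foreground pixels with a
4-neighbour background pixel; the reported value is the larger of the two
directed 95th percentiles (linear interpolation) of spacing-weighted
boundary-to-boundary nearest distances. This max-of-directed-percentiles
dialect is the common benchmark convention. HD95 on an empty mask raises an
error rather than returning a sentinel. Physical spacing is configurable and
defaults to 1 mm/px; distances are reported in pixels unless a spacing is
supplied.

## Known limitations

- Registration is affine only; strongly deformed or pathological anatomies
  would need a deformable step before the prior applies.
- Registration failure propagates directly into segmentation error; the
  pipeline records per-case transforms so this can be audited.
- The weights $\lambda_1, \lambda_2$ are fixed constants, not estimated; a
  kidney whose true extent lies far outside the prior support is penalized
  at the fringe (by design — that is the prior speaking), which bounds
  accuracy for atypical anatomy.
- The solver is 2-D per slice; no 3-D continuity is enforced across frames
  or slices.
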