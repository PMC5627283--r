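---
title: "Methods: tractography atlas-based analysis at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tractography atlas-based analysis at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package computes

Tractography atlas-based analysis (TABS) compares white-matter
microstructure between groups *along fiber tracts* rather than voxel by
voxel. The pipeline has three stages:

1. **Normalization and template construction.** Each subject's diffusion
   tensor volume is brought into a common (population) space by a
   nonlinear deformation estimated from a scalar *feature image* — FA,
   the largest Hessian eigenvalue of FA (hFA), or a T1-like structural
   channel — and the normalized tensors are averaged into a tensor
   template. Warped tensors are reoriented by the rotational part of the
   local Jacobian of the deformation so fiber directions stay
   anatomically consistent.
2. **Tract parameterization.** Deterministic streamline tractography on
   the template (FA threshold 0.2, per-step angle threshold 30°),
   ROI-logic bundle selection (AND/OR/NOT waypoints), and arc-length
   resampling to K corresponding points define a common along-tract
   coordinate system.
3. **Along-tract statistics.** The representative curve is mapped into
   each subject's native space through that subject's estimated
   deformation (pull-back fields map population points to native
   coordinates directly), the native FA is sampled at the K points, and
   group differences are tested pointwise with two-sample t statistics,
   1-D threshold-free cluster enhancement (TFCE), and permutation-based
   family-wise error (FWE) control; tract-averaged tests and ROC/AUC
   classification summarize sensitivity and specificity.

The scientific question the package is built to study is *how the choice
of feature image propagates into statistical sensitivity*: everything is
held fixed except the scalar channel driving registration.

Because no deposited data accompany this problem, the package ships a
synthetic world (`build_phantom()`, `make_cohort()`) in which the true
deformations, the true fiber geometry, and the true group effect are all
known, so every stage can be validated against ground truth.

# Similarity metrics

For two tensors with eigen-pairs $(\lambda_j, \epsilon_j)$ and
$(\lambda_j^*, \epsilon_j^*)$ sorted by descending eigenvalue:

* **OVL** $= \sum_j \lambda_j\lambda_j^* (\epsilon_j\cdot\epsilon_j^*)^2
  \big/ \sum_j \lambda_j\lambda_j^*$ — 1 iff the eigen-structures
  coincide.
* **DTED** $=\lVert D_a - D_b\rVert_F$, **DVED**
  $=\lVert \mathrm{dev}(D_a)-\mathrm{dev}(D_b)\rVert_F$ with
  $\mathrm{dev}(D) = D - \tfrac{\mathrm{tr}D}{3}I$. These satisfy the
  exact Pythagorean split
  $\mathrm{DTED}^2 = \mathrm{DVED}^2 + 3(\Delta\mathrm{tr}/3)^2$, which
  the tests assert instead of the (false) ordering DTED ≥ DVED.
* **AI** $=\arccos|\epsilon_1\cdot\epsilon_1^*|$ (degrees by default),
  **COH** $=|\epsilon_1\cdot\epsilon_1^*|$.
* **FA accuracy/precision** per voxel over N normalized images:
  $|\frac1N\sum_i \mathrm{FA}_i - \mathrm{FA}^{GT}|$ and
  $|\frac1N\sum_i (\mathrm{FA}_i - \mathrm{FA}^{GT})^2|$.
* **corrFA**: Pearson correlation of FA over a region for every
  unordered image pair.

**Where OVL is meaningful.** OVL is undefined up to the choice of
eigenbasis wherever eigenvalues are degenerate: in an isotropic voxel
*any* orthonormal basis diagonalizes the tensor, and two independently
computed bases give OVL anywhere in $[\lambda_1^2/\sum\lambda_j^2,\,1]$.
All OVL (and corrFA) summaries in this package are therefore taken over
white matter (FA ≥ 0.2), mirroring the brain/WM-ROI evaluation any
real study would use. For the same reason the synthetic bundles carry
*distinct* eigenvalues (1.7, 0.4, 0.2)×10⁻³ mm²/s with a smoothly varying
secondary axis: real white matter almost surely has distinct eigenvalues,
and a transversely isotropic phantom (λ₂ = λ₃) would cap OVL near 0.95
even under perfect alignment, making round-trip criteria untestable.

# The synthetic world

* **Phantom** (default): 48³ voxels of 2 mm, three tubes in an isotropic
  background (eigenvalue 0.7×10⁻³): a straight corticospinal-like tract,
  a callosal-like arc, and a cingulum-like S-curve (radius 3.5–4 mm,
  FA ≈ 0.8 inside). Tensors point along the centerline tangent of the
  nearest centerline sample. The T1-like channel is homogeneous (1.0)
  inside white matter — deliberately reproducing the premise that
  structural contrast carries little WM-internal information — and a
  smooth seeded texture (0.55 ± 0.08) outside. The atlas provides one
  tube mask per bundle plus a mid-tract waypoint slab.
* **Subject variability**: each subject is the phantom warped by a random
  sinusoidal displacement field, component $c$ being
  $A_c \sin(2\pi f_c (x\cdot d) + \phi_c)$ with per-axis amplitudes
  0.5–1.5 mm and frequencies 0.005–0.02 cycles/mm (drawn uniformly).
  The constructor enforces $\lVert\nabla u\rVert < 0.9$ so every field is
  invertible. These magnitudes give ~1–3 voxels of peak anatomical
  displacement, a scale typical of residual inter-subject variability
  after coarse alignment.
* **Group effect**: group B has its radial eigenvalues rescaled inside a
  chosen bundle's arc-fraction interval (default [0.4, 0.6]) so that FA
  drops by exactly δ (default 0.1) — applied in anatomical space *before*
  warping, so the pipeline must undo the warp to localize it.
* **Noise**: none by default (unit tests); tensor-component jitter or a
  full Rician-DWI round trip (30 golden-angle directions, b = 1000 s/mm²,
  5 b0s, SNR 20) are available.

What a green test does *not* establish: the phantom has no crossing-fiber
partial volume inside tubes, no susceptibility distortion, no spatially
varying noise, and its "T1" is a caricature. Green means the algorithms
are correct and the pipeline logic is sound at desk scale, not that the
effect sizes transfer to human cohorts.

# Registration engine

A single bespoke engine stands in for the FLIRT/FNIRT pair, because the
scientific object of study is the *feature image under a fixed engine*,
not the engine itself.

* **Affine**: 12 parameters acting about the FOV center, mean-squared
  intensity difference, multiresolution (never coarser than 16
  voxels/axis). Optimization is Nelder–Mead (with a BFGS warm start and
  restart-from-carried-parameters, keeping the better): the analytic
  gradient of a trilinearly interpolated objective — the interpolated
  grid gradient — is only approximately the objective's true derivative,
  which stalls quasi-Newton methods in voxel-scale wiggles. Accuracy is
  assessed as mean *point-map* displacement error, because
  rotation/translation decompositions trade off freely below the
  interpolation-bias floor (~0.1 voxel).
* **Nonlinear**: cubic B-spline free-form deformation; control spacing 4
  voxels (one knot per 8 mm at 2 mm resolution — half the shortest
  wavelength the subject warps contain); 3 pyramid levels with 60/40/25
  gradient-descent iterations (backtracking line search, step measured in
  mm of maximal control motion); bending penalty = 10⁻⁴ × mean squared
  second difference of the control coefficients; both images smoothed by
  1 voxel within each level (sharp binary-like FA tubes otherwise make
  the grid gradient inconsistent with the interpolant and descent
  stalls). The lattice lives in world coordinates, so coefficients
  transfer unchanged across pyramid levels. These defaults were chosen
  once while building the engine and then frozen.
* **Groupwise**: subject i's normalization field is the arithmetic mean of
  its pairwise fields to every other subject (`group_iters` rounds,
  default 1 — the iteration count is a config key because the source
  procedure does not state one).
* **Composition / inversion**: dense composition by sequential point
  mapping on a declared output grid; inversion by fixed-point iteration
  (tolerance 0.01 voxel, max 50 iterations), with the residual attached.

Ground-truth recovery is evaluated on white-matter voxels: an SSD match
on a scalar feature carries no information about displacement inside the
uniform background, so no registration of this class can recover it
there; the bending penalty merely interpolates smoothly.

# Numerical choices and edge cases

* Tensor storage order is fixed package-wide as lower-triangular
  (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz); eigenvector signs are canonicalized
  (first non-negligible component positive) and all direction metrics use
  absolute dot products, making the sign convention inert.
* Tensor interpolation during warping is log-Euclidean by default
  (positive-definiteness preserved); Euclidean is available for a
  strict-literal mode. Reorientation is finite-strain by default, PPD
  optional; the two agree to <10⁻⁶ on pure-rotation fields.
* "Inverse" fields in the simulated deformation family are exact
  negations — the only construction that satisfies the stated per-voxel
  sum-to-zero identity *exactly* (bitwise). Negation equals the true
  inverse only to first order; the composition residual is computed per
  pair and reported. It scales like $|u|\,|\nabla u|$ and is below 0.1
  voxel for amplitudes ≲ 1 mm at the default frequencies.
* Out-of-volume samples during warping are border-replicated but masked
  out; replicate-fill keeps registration objectives smooth where zero-fill
  would create artificial edges.
* The optimal-point-match step of parameterization is realized as a
  medoid-referenced orientation flip plus equal arc-length fractions (the
  correspondence minimizing summed endpoint distance to the bundle
  medoid); the interface isolates this choice so curvature-based matching
  could be swapped in.
* The tracker evaluates the 30° angle criterion per step (default step =
  half a voxel), seeds every suprathreshold voxel center, and discards
  streamlines shorter than 10 mm. Tube phantoms have rounded end caps
  that carry the end tangent, so a streamline legitimately runs about one
  tube radius past the end of an open centerline.
* TFCE uses the standard published defaults E = 0.5, H = 2, dh = 0.1,
  applied in 1-D with extent = run length in points; two-tailed inference
  takes the maximum of the two one-tailed maps. Permutation p-values are
  `(1 + #{null ≥ obs}) / (n_perm + 1)`; small groups switch to exact
  enumeration automatically.
* The pooled-variance t-test is the default (Welch optional); a point
  with zero pooled variance is reported as degenerate, not infinite.
* AI is reported in degrees by default (a config switch provides
  radians); corrFA pairs every unordered image pair (pairing against the
  template instead is exposed as an option).

# Known limitations

* The registration engine recovers roughly 60–80 % of a 1–2 mm synthetic
  deformation on the phantom; it is a desk-scale stand-in, not a
  competitor to FNIRT/ANTs.
* Histogram and ROI summaries pool voxels over image pairs; no mixed
  model accounts for within-subject correlation (the source procedure's
  ANOVA has the same property).
* The Type-I calibration of the permutation test runs on synthetic null
  *profiles* at the statistics interface (200 replicates, n_perm = 99);
  calibrating through 200 full imaging pipelines would take hours for no
  additional inferential content, since the profile distribution is the
  only input the test sees.
* Single-shell tensor model only; no eddy/motion correction, no brain
  extraction, no probabilistic tractography.
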