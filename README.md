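# tractatlas

Tractography atlas-based analysis (TABS) of diffusion tensor images at
desk scale, with a fully synthetic ground-truth world for validating
every stage of the pipeline.

## The problem

Along-tract analysis compares white-matter microstructure (typically
fractional anisotropy, FA) between groups at corresponding points along
fiber bundles. Its accuracy hinges on the nonlinear deformation that maps
each subject into a common space — and that deformation is estimated from
a scalar *feature image*: the FA map itself, the largest eigenvalue of
the Hessian of FA (hFA), or a T1-like structural channel. This package
implements the whole chain so the effect of the feature-image choice on
statistical sensitivity can be studied under controlled conditions:

- **Tensor core** — symmetric 3×3 tensor volumes (lower-triangular
  storage Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), eigen-decomposition, FA,
  Euclidean / log-Euclidean template averaging, log-linear tensor fitting
  from simulated diffusion-weighted signals.
- **Feature images** — FA, hFA (Gaussian-smoothed Hessian in world mm
  units), T1.
- **Registration** — affine and cubic B-spline free-form deformation
  (SSD + bending energy, multiresolution), groupwise mean-deformation
  normalization, dense transform composition, fixed-point field
  inversion.
- **Deformation simulation** — balanced families of invertible sinusoidal
  fields (each field paired with its exact negation, so the per-voxel
  vector sum is identically zero), tensor warping with finite-strain or
  PPD reorientation.
- **Similarity metrics** — OVL, FA accuracy/precision, DTED, DVED, AI,
  COH, corrFA; ROI tables, histograms, ANOVA with Bonferroni pairwise
  contrasts, Wilcoxon matched-pairs utility.
- **Tractography** — deterministic streamline tracking (FA ≥ 0.2,
  30° per-step angle), AND/OR/NOT bundle selection, arc-length
  parameterization with medoid-referenced point correspondence,
  inverse mapping to native space; TCK and TRK file support.
- **Along-tract statistics** — pointwise pooled-t, 1-D threshold-free
  cluster enhancement (E = 0.5, H = 2, dh = 0.1), permutation
  family-wise-error control (max-statistic null), tract-averaged tests,
  ROC/AUC.
- **Synthetic data** — a 48³ three-bundle tensor phantom, per-subject
  anatomical variability via random invertible warps, a localized FA
  group effect of configurable size, optional Rician-noise DWI
  simulation.

Along a tract, the group difference at point k is tested with a pooled
two-sample t statistic; the profile t(k) is enhanced as
TFCE(k) = Σ_h extent(k, h)^E · h^H · dh over thresholds h up to t(k),
and corrected p-values come from the permutation distribution of the
maximum |TFCE| (p_k = (1 + #{null ≥ |TFCE_k|}) / (n_perm + 1)).

## Worked example

```r
library(tractatlas)

# ground-truth phantom and one simulated "subject"
phantom <- build_phantom()
fields  <- generate_sinusoid_family(1, phantom$tensor$shape,
                                    phantom$tensor$affine, seed = 1)
subject <- warp_tensor_volume(phantom$tensor, fields[[1]])

# normalize the subject back using its FA map as the feature image
gt_fa  <- fa_map(phantom$tensor)
sub_fa <- fa_map(subject)
field  <- register_nonlinear(sub_fa, gt_fa)
normalized <- warp_tensor_volume(subject, field)

# how well did we do? OVL against ground truth over white matter
o  <- ovl(normalized, phantom$tensor)
wm <- gt_fa$mask & gt_fa$values >= 0.2
cat(sprintf("SSD before/after: %.5f / %.5f\n",
            attr(field, "ssd")[1], attr(field, "ssd")[2]))
cat(sprintf("mean WM OVL vs ground truth: %.4f\n",
            mean(o$values[wm & o$mask])))
```

Output from this exact script:

```
SSD before/after: 0.00226 / 0.00081
mean WM OVL vs ground truth: 0.9994
```

The registration reduced the FA mismatch by about two thirds, and the
normalized tensors agree with the ground truth almost perfectly in
eigen-structure (OVL = 1 means identical eigenvalue–eigenvector pairs;
values this high mean the warp and the tensor reorientation are both
correct). Running the end-to-end group analysis
(`make_cohort()` → `normalize_cohort()` → `tabs_along_tract()`) with a
FA reduction of 0.1 injected on the middle fifth of the arc bundle
(15 subjects/group) localizes the effect with Jaccard ≈ 0.9 against the
true interval and classifies the groups with AUC ≈ 1.

## Command line

A thin CLI ships in `inst/cli/tractatlas`:

```sh
Rscript inst/cli/tractatlas synth --out out/ --n-pairs 10 --seed 1
Rscript inst/cli/tractatlas feature --tensor dt.nii.gz --kind hFA --sigma 2 --out hfa.nii.gz
Rscript inst/cli/tractatlas register --moving sub.nii.gz --fixed ref.nii.gz --out field.nii.gz
Rscript inst/cli/tractatlas track --tensor template.nii.gz --out bundle.tck
Rscript inst/cli/tractatlas evaluate --gt gt.nii.gz --normalized dir/ --out eval.csv
Rscript inst/cli/tractatlas stats --profiles profiles.csv --labels labels.csv --n-perm 1000 --seed 1
```

Volumes are NIfTI-1 (tensors as 6-component 4-D images, displacement
fields as 3-component 4-D images, mm), affines are 4×4 whitespace text,
streamlines are TCK (primary) or TRK.

See `vignettes/tabs-methods.Rmd` for the model, parameter defaults and
their rationale, what the synthetic world does and does not emulate, and
known limitations.
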