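---
title: "Quantifying 3D proliferation patterning against facial morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D proliferation patterning against facial morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Light-sheet fluorescence microscopy of cleared mouse embryos yields, for a
single specimen, both its 3D morphology and the 3D positions of every
proliferating cell (a mitotic marker such as phospho-histone H3 against a
pan-nuclear stain). Relating the two quantitatively requires a chain of
image-analysis steps: converting anisotropic slice stacks to isotropic
volumes, registering specimens into common spaces, building per-age
consensus atlases, turning binary cell maps into normalized proliferation
heatmaps, and then asking statistical questions — does proliferation
concentrate where the face is growing? does the spatial pattern of
proliferation covary with shape across individuals? can it separate
genotypes? `prolifatlas` implements that chain end to end, together with a
synthetic phantom generator so every stage can be validated against known
ground truth.

## The phantom cohort

Because volumetric embryo datasets of this kind are not generally
deposited, the package ships a generator whose output has the same
*structure* as the real study design: ordered half-day age groups (E10 to
E11.5, staged by tail-somite count 8–20), five specimens per group, tissue
segmentations with three classes (background, mesenchyme, neural
ectoderm), binary nucleus and proliferating-cell maps, and two landmark
sets (5 head landmarks, 37 face landmarks).

The geometry is deliberately minimal: a superellipsoid head with an
interior neural-ectoderm core, plus three spheroid prominence lobes — a
frontonasal analog on the anterior midline and a left/right maxillary
pair. Growth across stages scales the lobes by an analytic field
(default: frontonasal +15% per stage, maxillary +5%), so the voxels added
between consecutive stages — the ground-truth "expansion mask" — are known
exactly. Proliferation hotspots sit at the growth sites, extend to the
outgrowing surface (1.15 lobe radii) and have excess proportional to each
lobe's growth rate; the baseline proliferative fraction is 0.16, matching
the 14–18% range typical of facial mesenchyme at these stages. Nuclei are
a jittered hard-core lattice of small blobs (so nucleus volumes, rather
than counts, carry the signal, as in dense nuclear stains), and
boundary jitter, per-specimen size variation and landmark jitter provide
realistic nuisance variation.

Two generator choices deserve explanation:

* **Physical scale.** The default voxel size is 25 µm, so a 96³–128³ grid
  spans 2.4–3.2 mm — the scale of a real E10–E11.5 head. This matters
  because the analysis parameters are physical: a 0.15 mm averaging
  window and a 0.39 mm surface shell are meaningful fractions of a
  millimetre-scale face, and would swallow a face simulated at a few
  hundred micrometres.
* **Landmark coverage.** The 37 face landmarks are distributed over the
  frontonasal lobe (13), the maxillary lobes (8 + 8) and the head surface
  between the prominences (8). A landmark set confined to the growing
  lobes would let the similarity (size-removal) registration absorb the
  growth signal itself — an artifact of the phantom's minimal geometry
  that the spread-out set avoids, just as the real landmark set spans the
  whole face.

What the phantom does *not* emulate: imaging artifacts (blur, signal
loss, refraction), nucleus texture, segmentation errors, or biological
asymmetries. Tests passing on phantoms therefore validate the pipeline's
*computational* behaviour — registration accuracy, statistical
calibration, recovery of planted effects — not robustness to acquisition
pathology.

## Pipeline stages and their parameters

`run_pipeline()` chains the stages; each is exported on its own.

**Isotropization and I/O.** Stacks are resampled with an output depth of
`ceiling(extent / spacing)` — tissue is never truncated — with nearest
neighbour mandatory for labels and binary maps. NIfTI carries spacing and
origin in the qform; TIFF stacks use a `<name>.spacing.json` sidecar
because TIFF z-spacing tags are unreliable across writers. Voxel centres
are the world anchor: `world = origin + index * spacing` (0-based).

**Atlas registration.** Within each age group, specimens are pre-aligned
to a reference with a rigid transform fitted to the 5 head landmarks
(closed-form absolute orientation), then registered groupwise-affinely:
the mean starts as the reference segmentation, every specimen is
registered to it by multi-resolution BFGS on a mean-squared-difference
metric over Gaussian-smoothed tissue indicator images, the mean is
recomputed by per-voxel majority vote, and the loop repeats until fewer
than 0.1% of mean voxels change label. Indicators (not intensities) are
the right metric here because the inputs are segmentations. Defaults —
three pyramid levels (4×, 2×, 1×), tens of BFGS iterations per level, at
most ten outer iterations — are desk-scale choices; all are exposed.
Majority-vote ties are broken deterministically in favour of the higher
label code (neural ectoderm over mesenchyme over background). No scaling
occurs in this chain; size is removed only in the bulk (similarity)
stage, so size is never removed twice.

**Bulk space and heatmaps.** All specimens (and, where used, their
midsagittal mirrors) are mapped to one reference by a similarity
transform fitted to the 37 face landmarks — translation, rotation and
uniform scale, i.e. Procrustes-style size removal. Proliferation maps are
binary-voxel box means over a 0.15 mm cube (converted to the nearest odd
voxel count; borders use shrinking windows), normalized by clipped linear
rescaling between the 1st and 99th in-tissue percentiles (linear
interpolation between order statistics; a constant map degenerates to
zero). Group proliferation atlases average the normalized maps of a group
and their mirrored copies. The facial analysis mask keeps voxels voting
mesenchyme in strictly more than 30% of the registered segmentations and
within 0.39 mm of that primary mask's surface (Euclidean distance
transform; beyond-grid space counts as background); a user ROI can be
intersected where a manually refined mask would be used. The mutant-line
variant instead majority-votes, closes with a cubic structuring element
(default 40 voxels, rounded to odd) and then shells.

**Shape change and its correlation with proliferation.** Each specimen of
age N is compared voxel-wise with the age-(N−1) consensus mesenchyme,
coding +1 (outward), −1 (inward) and 0. Outward/inward proportions are
reported over the face mask; Pearson's r between the differential volume
and the previous age's proliferation atlas is computed over the facial
mesenchyme — the face mask intersected with the previous-age atlas
mesenchyme, which anchors the correlation to voxels where the prior-age
heatmap is supported. |r| is the group summary.

**Voxel-based morphometry.** Each age-N specimen's segmentation is
registered deformably to the age-(N−1) atlas by Gaussian-regularized
demons on the tissue indicators (multi-resolution; update smoothing σ = 3
voxels, field smoothing σ = 0.5, per-iteration step cap 1.25 voxels, with
the classical intensity/spacing normalization in the force denominator).
The resulting field, on the atlas grid, maps atlas points into the
specimen, so its Jacobian determinant `det(I + ∇u)` (central differences
interior, one-sided at borders, world units) measures specimen volume
relative to the atlas — above 1 where the specimen has locally expanded.
A one-sample t statistic of log J against zero per voxel (df = n−1;
log J treats expansion and contraction symmetrically; a raw-J option
exists) gives the t-map, thresholded one-sided into a shape-significance
mask. `significance_mask()` defaults to the Student quantile at α = 0.05,
but the pipeline passes `t_crit = 3.2`: at five specimens per group the
α = 0.05 quantile (t ≈ 2.1, df 4) also sweeps up shared registration
bias (about a quarter of all tissue voxels), whereas t ≈ 3.2 selects
roughly the top decile of voxels, concentrating the mask on the
strongest consistent expansion — the operating point at which such
stage-expansion parametric maps are usually read. The fraction of positive-Jacobian tissue voxels is attached to each
registration as a diagnostic, with a warning below 99%.

**The random-mask null.** To ask whether proliferation inside the
significance mask exceeds chance, each specimen's warped proliferation
map is averaged inside the mask and compared with `R = 100` equally-sized
voxel sets drawn uniformly without replacement from the atlas mesenchyme.
The empirical p uses the add-one rule, `p = (#{null ≥ obs} + 1)/(R + 1)`,
so its floor is 1/101; the stricter "outside the null range" flag records
an observed mean exceeding every replicate. Sampling voxel-wise (without
spatial contiguity) mirrors thresholding voxels by randomly sampled
t-values; a contiguity-preserving alternative can be had by passing a
translated copy of the mask as `sig_mask`. The percent-increase summary
is `100·(mean_sig − mean_rand)/mean_rand`, one decimal.

**Landmark and proliferation morphometrics.** Generalized Procrustes
analysis (centre, unit centroid size, rotate to the iterated mean;
convergence 1e−8) yields shape coordinates; PCA is a centred SVD with a
deterministic sign convention (largest-magnitude loading positive). The
proliferation block for PLS/PCA/SVM is built by averaging each
specimen's normalized in-mask proliferation over cubic cells (default 8
voxels = 0.2 mm): pooling suppresses voxel-level binomial noise that
otherwise drowns the between-specimen signal at these sample sizes,
while preserving the spatial pattern. Two-block PLS takes the SVD of the
cross-block covariance of the column-centred blocks; r is the Pearson
correlation of the first latent pair; the permutation test shuffles the
proliferation block's rows with the shape block fixed (one-tailed on r,
add-one rule; z is the normal-theory standardization of the permuted
distribution). Stage residualization regresses each column on somite
count. Genotype separation z-scores the first five proliferation PC
scores and fits a linear SVM (hinge loss, C = 1; the libsvm solver runs
to its own convergence tolerance, so the `max_iter` argument is accepted
for interface compatibility and ignored); F1 with wild type positive is
evaluated on the training task — deliberately matching how such small
cohorts are reported, and optimistic by construction — and its
significance comes from a 1000-fold label permutation.

## Numerical conventions and degenerate inputs

* Percentiles everywhere use linear interpolation between order
  statistics (type 7); exclusion bounds are strict, so 100 equal-volume
  components survive the 1st/99th-percentile cell filter unchanged.
* Component labelling is deterministic (raster-scan order);
  connectivity defaults to 26 for nuclei.
* Empty differential masks, constant maps, all-coincident landmark
  configurations, single-class SVM labels and sub-minimal landmark counts
  raise informative errors rather than propagating NaNs; both-empty Dice
  is defined as 1.
* Axis profiles place each nucleus voxel by projecting its world position
  on the requested axis, rescaled over the ROI's extent; K = 1 reduces to
  the global proliferative fraction. The Kolmogorov–Smirnov uniformity
  test is two-sample against nucleus-voxel positions by default (this
  controls for tissue extent varying along the axis); the literal
  one-sample test against Uniform(0,1) is available.
* Seeded determinism: a phantom spec plus seed reproduces a cohort bit
  for bit; permutation and null draws accept explicit seeds and restore
  the caller's RNG state.

## Problem sizes

The test-suite and acceptance experiments run on desk-scale grids chosen
once: 96³ voxels (2.4 mm at 25 µm) for the end-to-end cohort experiment,
64³ for single-stage experiments, smaller analytic fixtures elsewhere.
Registration iteration counts in `run_pipeline()`'s defaults are
correspondingly reduced from production settings; all are arguments.

## Known limitations

* The demons implementation is a first-order (non-diffeomorphic) scheme
  with Gaussian regularization; very large deformations can fold
  (J ≤ 0), which the positive-Jacobian diagnostic reports.
* Training-set F1 under label permutation can tie with the observed score
  when a permuted labelling happens to be linearly separable; with small
  cohorts this makes the permutation p conservative. Cross-validated
  scores would behave differently and are not implemented.
* The box-window density at tissue boundaries averages over background
  voxels (boundary dilution); comparisons across regions of different
  surface proximity inherit this.
* With cohorts of ~20 specimens, the PLS permutation test has limited
  power: the first-pair latent correlation is close to 1 even for
  permuted blocks, and at the 64-cube phantom scale the permutation p
  falls below 0.05 in only roughly two-thirds of simulated cohorts at
  the default hotspot strength. Detection is reliable, not guaranteed,
  at desk-scale problem sizes.
* `run_pipeline()` assumes cohorts share a grid (as the phantom
  guarantees); real data should be isotropized and cropped to a common
  grid first.

## A short walk-through

```r
library(prolifatlas)

spec <- phantom_spec(grid_shape = 64, n_per_group = 5, seed = 1)
ch <- generate_cohort(spec)
res <- run_pipeline(ch, do_vbm = FALSE, seed = 1)

res$shapechange          # per-specimen outward/inward fractions and r
res$morpho$pls           # proliferation-shape PLS with permutation p
plot_pls(res$morpho$pls, color = res$metadata$somites)
```
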