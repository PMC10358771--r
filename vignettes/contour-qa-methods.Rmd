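---
title: "Contour accuracy metrics and MRI standardisation: methods and design choices"
author: "contourQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour accuracy metrics and MRI standardisation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contourQC)
```

## Scope and problem

Deep-learning auto-segmentation of the upper-abdominal organs-at-risk on
multi-sequence MRI is evaluated clinically by comparing auto-segmented
contours with manual reference contours (MRC). `contourQC` implements the
evaluation side of that workflow as a reusable toolkit: six
volumetric/surface accuracy metrics, quality categorisation and an editing
scorecard, the MRI intensity-standardisation chain used to prepare
multi-sequence inputs, the training-time augmentation transforms, and a
synthetic phantom generator that makes every computation testable without
clinical data. The segmentation network itself is out of scope; the
package evaluates and prepares, it does not segment.

All objects carry explicit physical geometry: voxel spacing in mm along
(x, y, z) with z the slice axis. Any operation pairing two masks verifies
shape and spacing before computing.

## The six metrics and their conventions

For an auto mask $A$ and reference mask $R$ with surfaces $\partial A$,
$\partial R$:

* **DSC** $= 2|A \cap R| / (|A| + |R|)$; defined as 1 when both masks are
  empty (agreement on absence), 0 when exactly one is empty.
* **MDA** (mean distance to agreement): the area-weighted mean of the
  *pooled* directed nearest-surface distances, i.e. the average symmetric
  surface distance. Pooling both directions makes MDA symmetric in its
  arguments by construction.
* **HD95%**: the maximum of the two *directed* area-weighted
  95th-percentile distances. The alternative pooled-percentile convention
  exists in the literature; both are available
  (`metricConfig(hd_convention=)`), directed-max is the default because it
  is the common radiotherapy usage. With `hd_percentile = 100` it is the
  exact Hausdorff distance.
* **PVD** $= 100\,(V_A - V_R)/V_R$ (volumes in cc); negative means the
  auto contour is under-drawn.
* **sDSC** (surface Dice at tolerance $\tau$, default 2 mm): the fraction
  of the combined boundary area lying within $\tau$ of the other boundary.
  The 2 mm default approximates expected inter-observer variation in
  manual abdominal contouring.
* **APL / rAPL**: the added path length is the length of reference
  contour that must be redrawn: per axial slice, the in-plane reference
  contour edges farther than $\tau$ (in-plane distance) from the auto
  contour of the same slice contribute their length; a slice with
  reference but no auto contour contributes its full perimeter. APL is in
  mm — it is a slice-wise *length*, matching how contours are actually
  edited slice by slice. A `surface3d` mode applies the same rule to 3D
  surface elements but then reports an *area* in mm² and is deliberately
  excluded from rAPL, which is always APL(slice2d) divided by the
  *reference* organ volume in cc. Normalising by the reference (rather
  than the auto) volume anchors the editing effort to the organ's true
  size; volume-normalisation makes editing effort comparable between an
  esophagus of a few cc and a liver of hundreds of cc.

Ambiguities in common usage (pooled vs directed HD, which volume divides
APL) are resolved as above and switchable in `metricConfig()`.

### Surface representation and exactness

Boundaries are represented as exposed voxel faces — faces between an
inside and an outside voxel, the volume border counting as outside — with
the face centre as position and the physical face area as weight. This
representation is deterministic and lets every distance be checked against
brute force, unlike marching-cubes meshes.

Face centres live on the *half-integer lattice* (coordinates that are
multiples of half the voxel spacing). Nearest-neighbour distances between
the two boundaries are therefore computed with an exact Euclidean distance
transform (Felzenszwalb/Huttenlocher, implemented in C++ with anisotropic
step sizes) on that doubled lattice: the result equals the all-pairs
brute-force nearest distance to floating-point precision, not a grid
approximation. The test suite asserts agreement within $10^{-6}$ mm
against an independent all-pairs implementation on hundreds of random
anisotropic mask pairs, and the same property holds slice-wise for the 2D
distances inside APL.

Empty-mask policy: DSC and PVD follow the rules above; surface metrics on
an empty mask are *flagged missing*, never silently zero — a missed organ
must not be rewarded. APL remains defined whenever the reference is
non-empty (a fully missing auto contour costs the whole reference
perimeter).

## Quality categories, scorecard, aggregation

Each metric value is categorised **best / good / sub-optimal** with
inclusive thresholds (defaults: best at DSC ≥ 0.9, MDA ≤ 1.5 mm,
HD95 ≤ 5 mm, |PVD| ≤ 3 %, sDSC ≥ 0.85, rAPL ≤ 5 mm/cc; good at 0.8, 3 mm,
10 mm, 6 %, 0.75, 10 mm/cc). PVD is graded on its absolute value: over-
and under-drawn contours both need edits, and a one-sided threshold would
be meaningless for a signed quantity. `gradeTables()` validates that every
best threshold is at least as strict as its good counterpart, and
categorisation is monotone: improving a value can never demote it.

The 1–6 editing scorecard maps the editing burden of one contour to an
ordinal score (1 = no edits … 6 = redo). The published criteria mix a
slice count and a fraction ("20 or < 50 %"); the implemented rule takes
the worse of a count-based score (0 → 1; < 5 → 2; < 10 → 3; ≥ 10 or ~20
under half → 4; > 50 % → 5; > 80 % → 6) and a floor implied by the edit
kind (deletion/expansion → 2, incomplete segmentation → 3,
junction/hilum → 4, majority redraw → 5, full redo → 6), so ties resolve
toward the worse score and the result is monotone in the number of edited
slices.

Aggregation conventions (`aggregateMetrics()`):

* per-organ, per-model means across cases;
* per-model overall means as the **unweighted** mean of the 12 per-organ
  means — each organ counts once regardless of its size or case count
  (this is the arithmetic that reproduces the bundled summary tables);
* radar-ready normalisation: each per-organ mean divided by the maximum
  absolute value of that metric across all organs and models, so the
  worst cell maps to magnitude 1. The absolute value handles the signed
  PVD.

A single per-contour category (for "x % of contours are acceptable"
statistics) is the majority vote over the six per-metric categories with
ties resolved toward the worse label; no standard rule exists for this
reduction, so the choice is documented and deliberately conservative.

## Intensity standardisation chain

`standardizePipeline()` applies, in order:

1. **Bias-field correction** (`correctBiasField()`). MRI bias is a smooth,
   strictly positive multiplicative field. The estimator works in the log
   domain on gradients: between neighbouring same-tissue voxels the
   log-intensity difference equals the bias difference, while tissue
   boundaries appear as sparse large spikes. Adjacent-voxel log
   differences are robustly trimmed (beyond 4 MAD from the median) and
   least-squares matched by the differences of a tensor-product
   polynomial (per-axis degree 3 by default); the integrated field is
   normalised to unit geometric mean over the foreground and divided out,
   with the output rescaled so the global mean is preserved exactly.
   Fitting gradients rather than intensities keeps genuine organ contrast
   out of the field estimate — the failure mode of a naive log-intensity
   fit. On phantoms with a known amplitude-0.3 field the residual
   field-induced coefficient of variation drops by over 90 % (the test
   suite requires ≥ 50 %).
2. **Anisotropic-diffusion denoising** (`denoiseAnisotropic()`):
   Perona–Malik diffusion with rational conductance
   $c(g) = 1/(1+(g/\kappa)^2)$ (exponential available) in an explicit
   conservative flux-difference scheme with zero-flux boundaries, which
   conserves the global mean exactly. Defaults: 5 iterations, $\kappa$ at
   the 90th percentile of the gradient magnitude (separating noise
   gradients from edges), time step at 80 % of the 3D stability bound
   $1/\left(2 \sum_d h_d^{-2}\right)$. A user-supplied step above the
   bound is an error, never a silent clamp; zero iterations is the exact
   identity.
3. **Median normalisation** (`normalizeToMedian()`): the volume is divided
   by the median intensity of foreground voxels, fixing the foreground
   median at 1. "Foreground" is a documented convention (the underlying
   clinical tool does not specify one): voxels above the larger of the
   5th percentile of nonzero intensities (excludes an exactly-zero air
   background) and 5 % of the 99.5th-percentile intensity (excludes noisy
   air). Both terms scale with the data, so the operation is invariant to
   positive global rescaling, and division preserves the rank order of
   intensities.

The Z-score step (`zscorePercentile()`) is kept separate because it
prepares *model input* rather than a standardised image: the mean and SD
are computed from voxels inside the closed [0.25, 99.75]
intensity-percentile window — so intensity outliers do not inflate the
moments — and the affine transform is applied to *all* voxels without
clipping. Whether statistics should be per volume or pooled across a
patient's acquisitions is ambiguous in practice; per-volume is the
default and `stats_from =` provides the pooled per-patient mode.

## Augmentation transforms

* **Gamma transform** (`gammaTransform()`): with probability 0.3 the
  intensities are mapped to [0, 1], raised to $\gamma \sim U(0.7, 1.3)$,
  and mapped back. Applying the exponent after range-normalisation (and
  undoing it after) makes the operation well defined for Z-scored,
  negative-valued input and preserves the intensity extremes and the rank
  order. Constant volumes are a documented no-op.
* **Elastic deformation** (`elasticDeform()`): independent per-axis
  displacements drawn uniformly within ±4 mm on a coarse control grid
  (50 mm spacing) and interpolated to voxel resolution with cubic
  B-splines; the B-spline partition of unity bounds the field by the
  control amplitude, and the coarse grid keeps it smooth. The magnitude
  and grid are package choices — the training protocol that motivated the
  transform only calls the deformation "minor" — sized to be small
  relative to abdominal organ scale. Image and every mask are warped by
  the *same* field (backward mapping; linear interpolation for the image,
  nearest-neighbour for masks, so no label values are invented);
  out-of-volume samples are edge-clamped to avoid background bleed. Zero
  amplitude returns the inputs bitwise-identical.

Both transforms take an explicit per-call seed (falling back to the
config seed); the RNG state of the session is saved and restored around
each draw, so identical (input, seed) pairs give identical outputs and
the transforms can be replayed.

## The phantom generator

`makePhantom()` builds the study conditions synthetically: twelve organ
caricatures — ellipsoids (liver, spleen, stomach, kidneys, pancreas,
small bowel), straight tubes (aorta, spinal cord, esophagus, large
bowel), and a C-loop tube for the duodenum — placed disjointly in a
~157 × 157 × 120 mm field of view at the T1-like voxel spacing
(1.640625, 1.640625, 3) mm (a T2-like 1.1875 mm in-plane alternative is a
parameter). Organ volumes span roughly two orders of magnitude (esophagus
≈ 1.7 cc to liver ≈ 100 cc), because the organ-size spread is what drives
the volume-normalised metrics (rAPL) apart across organs. Intensities are
piecewise constant per organ (140–350, loosely tissue-ordered), times a
smooth multiplicative bias field (1 + 0.3 · smooth unit-normalised random
field with 80 mm correlation length — bias is a low-frequency coil/B0
artefact, so the correlation length is set to half the field of view),
plus Gaussian noise (SD 5, a few percent of tissue intensity). Overlap
between recipes is an error unless explicitly allowed (abutting organs
are representable via per-organ masks, not via a label map). Everything
is reproducible from (spec, seed).

`perturbMask()` provides controlled "auto" contours: voxel-quantised
translation (the realised mm shift is reported, keeping analytic expected
distances exact), 6-connected erosion/dilation, dropped superior slices,
and seeded boundary jitter. `makeBenchmarkSuite()` assembles 19 pairs
across seven families with expected metric values that are either
closed-form or derived from an all-pairs brute-force oracle that shares
no code with the production distance transform; each expected value is
tagged `analytic` or `oracle`.

What the phantom deliberately does **not** emulate: anatomically
realistic shapes, MR physics (Rician noise, motion, susceptibility),
inter-observer contour variability, or the intensity overlap of real
tissues. Tests passing on phantoms therefore demonstrate the correctness
of the *computations* (metrics, normalisation, augmentation) under known
ground truth — not clinical segmentation performance.

## Numerical choices and degenerate inputs

* Distance exactness: production distances must match brute force to
  1e-6 mm; the weighted percentile uses the inverse-CDF convention
  (smallest value reaching the requested cumulative weight).
* Geometry checks fail fast with the offending shapes/spacings named.
* Degenerate volumes: 1-voxel volumes pass through bias correction
  unchanged; constant volumes error in Z-score (zero SD) and are no-ops
  for gamma; empty masks are flagged, not errors, except where a metric
  is mathematically undefined.
* Problem sizes in the shipped tests: 12 × 12 × 8 grids for the
  brute-force equivalence ensemble (200 pairs), 20 × 20 × 16 for analytic
  cube cases, and the full 96 × 96 × 40 phantom for pipeline tests —
  sizes at which the independent oracles are exact and fast.

## Limitations

* NIfTI only; DICOM-RT structure sets, polyline contours, and
  registration are out of scope.
* A label map cannot represent overlapping organs; use per-organ files
  for abutting structures.
* The bias estimator assumes the field is well approximated by a
  low-degree polynomial across the field of view; strongly localised
  shading would need a finer basis.
* The median-normalisation foreground rule is a documented convention,
  not a reconstruction of any specific clinical tool's behaviour.
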