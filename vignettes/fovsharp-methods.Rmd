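---
title: "Measuring the resolution gain of small-FOV CT reconstructions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the resolution gain of small-FOV CT reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fovsharp)
library(dplyr)
```

## The problem

CT angiography of the lower extremities is usually reconstructed once, with
a field of view (FOV) wide enough to cover both legs. With a fixed 512 x 512
reconstruction matrix the in-plane voxel size is `FOV diameter / 512`, so a
whole-body FOV of about 423 mm yields 0.83 mm voxels while a side-specific
FOV of about 220 mm yields 0.43 mm voxels — from the *same* raw data. Since
modern detectors resolve structures well below 0.8 mm, the wide FOV throws
resolution away, and the below-the-knee (crural, pedal) arteries, whose
calibres approach the large voxel size, suffer most.

`fovsharp` quantifies that loss twice over, mirroring how such a claim is
established in practice:

* **objectively**, with an automated per-slice image-sharpness metric
  computed on geometrically matched large/small-FOV volume pairs, and
* **subjectively**, with the statistics of an ordinal reader study
  (ICC(2,k) interrater agreement, Wilcoxon and t tests on 5-point Likert
  scores).

Because clinical CTA volumes cannot ship with a package, a synthetic-data
module provides digital leg phantoms with FOV-dependent reconstruction
simulation and a calibrated reader-rating simulator, so every stage is
exercised end to end by code alone.

## The objective sharpness metric

For a reconstruction pair the pipeline is:

1. **Body segmentation.** An Otsu threshold on the full HU volume separates
   patient from air; only the largest 3-D connected component
   (26-connectivity) is kept, and fully enclosed holes are filled slice-wise
   (`body_mask()`).
2. **Bone segmentation.** A second Otsu threshold on the HU values inside
   the body separates bone from soft tissue; components below 50 voxels are
   discarded as speckle (`bone_mask()`). A fixed-HU cutoff (300 HU) is
   available as an escape hatch for volumes where contrast-filled vessels
   contaminate the upper class.
3. **Analysis ROI.** Sharp edges that carry no diagnostic information —
   object-to-air and tissue-to-bone boundaries — are excluded by removing
   all voxels within a margin (default 2 mm) of bone and eroding the body
   rim by the same margin (`analysis_roi()`). Contrast-filled vessels and
   their mural calcifications are deliberately *kept*: they are the
   structures whose sharpness is at issue.
4. **Grid matching.** The large-FOV volume is resampled onto the exact
   voxel positions of the small-FOV grid by cubic B-spline interpolation
   (`align_pair()`), so the two volumes can be compared voxel for voxel.
5. **Significant edges.** The per-voxel gradient magnitude
   `sqrt(gx^2 + gy^2)` (central differences, HU/mm) is computed per slice;
   an Otsu threshold on the gradient magnitudes inside the ROI — pooled over
   the volume by default — selects the "significant edges", suppressing the
   low-gradient noise floor (`significant_edge_mask()`).
6. **Scoring.** The slice sharpness is the sum of gradient magnitudes over
   the edge voxels (`slice_sharpness()`); `compare_pair()` scores both
   volumes under one identical mask set and edge mask (derived from the
   small-FOV volume by default), reports per-slice differences
   (small − large), and tests `small > large` with a one-sided unpaired
   t-test across slices.

### Choices the formula leaves open

* *Per-voxel magnitude, then sum.* The magnitude-then-sum reading matches a
  per-position gradient profile; the alternative `sqrt(sum(gx^2 + gy^2))`
  is monotone-related but not equal, and is available via
  `normalization = "mean"`-style config rather than silently substituted.
* *Edge threshold scope.* Pooled per-volume Otsu by default so all slices
  are scored on one scale; per-slice scope is available.
* *Mask source.* Masks and the edge mask come from the small-FOV (sharper)
  volume and are applied to both, which keeps the comparison strictly
  paired; a union-of-edges variant is provided.
* *Exclusion margin.* 2 mm by default. The margin must exceed the residual
  edge spread of the *large*-FOV volume on the analysis grid (roughly two
  large-FOV voxels: PSF plus interpolation support); at the study geometry
  (0.83 mm large voxels) 2 mm suffices, while strongly down-scaled
  geometries (tests use 2.5 mm voxels at a 128 matrix) need the margin
  scaled up accordingly, or residual air-boundary energy in the blurrier
  volume can dominate the score.
* *Statistics.* Slices of one volume are spatially autocorrelated; the
  per-dataset t-test is reported as-is, as is conventional for this kind of
  per-slice metric, and no correction is attempted.
* *Gradient operator.* Plain central differences in physical units, with
  one-sided differences at borders; no pre-smoothing, so the metric
  responds to the reconstruction's own noise/resolution trade-off only.

The metric is exactly invariant under constant HU offsets and exactly
linear under positive HU scaling (the Otsu threshold scales with the data),
and strictly decreasing under increasing Gaussian blur on noiseless
phantoms — the test suite asserts all three.

## B-spline resampling

"B-spline interpolation" unqualified means cubic in imaging practice, so
order 3 is the default (orders 0–5 are supported). Interpolation uses a
collocation prefilter, so sampling exactly at source voxel centres
reproduces the source values. For the cubic order the two free end
conditions are closed not-a-knot style (vanishing third-derivative jump at
the first and last interior knots), which makes the interpolant reproduce
polynomial images up to degree 3 *exactly* over the whole sample hull — the
property the test suite checks at 1e-6 — rather than only deep in the
interior as a mirror boundary would. Other orders use a whole-sample mirror
boundary. Target voxels outside the source hull are filled with air
(−1000 HU) and tracked in a validity mask; `align_pair()` errors when more
than 1% of target voxels fall outside, which cannot happen in the intended
direction (large FOV ⊇ small FOV). Resampling small onto large is permitted
but warns: it discards resolution.

Both reconstructions of one acquisition share the z-grid, so resampling is
in-plane only; slice positions are matched within a small tolerance and
mismatches are errors, not interpolated.

## The phantom and reconstruction simulator

`phantom_spec()` describes an axial leg cross-section: a soft-tissue body
ellipse (40 HU, default 160 x 140 mm), two cortical-bone circles (1200 HU,
tibia/fibula calibre), contrast-filled vessel circles (350 HU, radii
0.3–6 mm spanning femoral-to-pedal calibre) and optional mural
calcification arcs (800 HU) on vessel walls. Later structures overwrite
earlier ones, so calcifications (listed last) overwrite lumen. Vessels
drift slightly from slice to slice (defaults ±0.4 mm/slice) so neighbouring
slices are correlated but not identical. `render_phantom()` rasterises at
0.1 mm; `random_phantom_spec(seed)` draws valid random phantoms for
population-level checks.

`simulate_reconstruction()` models only what the FOV effect requires:

* Gaussian PSF with `FWHM = sqrt(psf_fwhm^2 + (aperture_k * voxel)^2)`,
  a fixed detector term (default 0.6 mm, matching a sub-millimetre
  collimated detector) plus a voxel-aperture term (`aperture_k = 1`) in
  quadrature — larger FOV ⇒ larger voxel ⇒ blurrier image;
* area-average down-sampling onto the reconstruction grid (each voxel
  averages the truth voxels whose centres fall in its footprint);
* additive white Gaussian noise (default 10 HU), seeded.

No filtered back-projection, kernels, beam hardening or dose modulation are
simulated; consequently the phantom demonstrates the *FOV-driven resolution
mechanism* and pipeline correctness, not absolute clinical metric values.
The package's simulated sharpness differences are in arbitrary summed
HU/mm units on synthetic anatomy and are not comparable to numbers measured
on clinical data. Noise is white rather than reconstruction-correlated,
vessel enhancement is static, and the per-slice anatomy varies only by
vessel drift — passing tests therefore show the method orders resolution
correctly and is internally consistent, not that clinical effect sizes are
reproduced.

The default study conditions are 20 random phantoms, 5 slices each,
reconstructed at 422.67 mm and 220.19 mm FOV on a 512 matrix (the study's
mean FOV diameters); the problem sizes in the tests (reduced 128-matrix
variants, 1–3 slices) were chosen so the full suite exercises every path on
desk-scale hardware.

## The reader-study statistics

Ratings live in long tables keyed by (exam, side, level, fov, reader) with
scores 1–5; score 1 means non-diagnostic. The analysis chain
(`run_subjective()`) is: non-diagnostic exclusion → ICC(2,k) on per-reader
data → reader pooling → per-segment summaries with paired tests.

* **Exclusion policy.** By default both FOV members of any
  (exam, side, level, reader) with a non-diagnostic rating are removed,
  preserving the pairing that the signed-rank and paired t-tests need;
  removing only the offending record is available (`"per-rating"`). The
  ICC step additionally omits targets left with an incomplete reader set —
  `icc2k()` itself refuses missing data rather than imputing.
* **ICC(2,k).** Two-way random effects, absolute agreement, reliability of
  the mean of k raters, from the ANOVA mean squares;
  confidence intervals via the F-based interval for the single-rater
  agreement coefficient, Spearman–Brown stepped up. Reliability bands:
  poor < 0.5 ≤ moderate ≤ 0.75 < good ≤ 0.9 < excellent. (An ICC of 0.82 is
  "good" under these bands, although the older Landis–Koch vocabulary would
  call it "almost perfect" — the banding above is what the package
  reports.)
* **Wilcoxon tests.** Both the signed-rank (small vs large FOV, paired) and
  the rank-sum test (right vs left side) use tie-averaged ranks and compute
  the *exact* permutation null by dynamic programming for n ≤ 25 — ordinal
  ratings are heavily tied, where the classical exact tables do not apply —
  switching to the tie-corrected normal approximation with continuity
  correction above. Two-sided p-values are twice the smaller tail, capped
  at 1.
* **Dual testing.** Mean-based t-tests are reported alongside the rank
  tests, as is common for Likert summaries; no multiple-testing correction
  is applied (α = 0.05 throughout), and the output metadata says so.

### The rating simulator

Scores are a discretised latent normal: each cell draws
`mean + sd * (sqrt(rho) * b + sqrt(1 - rho) * e)`, rounds to the nearest
integer and clips to [1, 5], where `b` is shared by all readers and both
FOVs of an (exam, side, level) and `e` is reader noise. `rho` (default 0.6,
a realistic "good agreement" level) sets both interrater agreement and the
small/large pairing correlation without touching the marginal moments. The
default calibration targets are the per-segment score means and SDs of a
100-exam lower-extremity CTA reader study (`reference_rating_moments()`);
because rounding and clipping bias the moments of a discretised normal, the
default `calibration = "score"` mode inverts the discretisation
numerically so the *simulated score* moments match the targets
(`calibration = "latent"` uses the targets as latent parameters directly).
Non-diagnostic ratings then arise naturally and almost exclusively at the
crural and pedal levels under the large FOV, where the latent means are
lowest.

## Degenerate inputs and numerical conventions

* Physical coordinates use the voxel-centre convention
  (`origin + index * spacing`, 0-based); the slice axis is the third index.
* Otsu thresholding requires at least two distinct values (two occupied
  bins); constant input is an error — except for the *gradient* Otsu, where
  a constant gradient yields an empty edge mask with a warning, since a
  featureless slice is a legitimate (zero-sharpness) observation.
* Otsu ties are broken towards the lowest threshold; the sharpness of a
  slice with an empty edge mask is 0, and such slices are excluded from
  volume means rather than counted as zeros.
* All randomness flows from explicit integer seeds through a private RNG
  stream that restores the caller's RNG state; equal seeds give identical
  volumes, tables and reports.
* NIfTI-1 is the canonical interchange format (values stored as float32,
  geometry in pixdim + sform); DICOM series must be converted upstream.

## Known limitations

* The bone-removal quality score (`bone_removal_quality()`) is an automated
  proxy for what is a visual judgement in practice; its component-size
  heuristic separating bone from calcification is resolution-dependent.
* Per-slice sharpness values depend on the number of edge voxels; the
  default summed metric is comparable between the two members of a pair
  (identical masks) but not across datasets with different anatomy.
* The simulator omits reconstruction-kernel effects, correlated noise and
  contrast dynamics (see above), so absolute effect sizes are synthetic.
* In-plane morphology: the bone/air exclusion margin is applied per slice;
  at typical slice spacings (≥ the margin) a 3-D ball adds nothing, but for
  near-isotropic thin-slice data a through-plane margin would be the better
  choice.
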