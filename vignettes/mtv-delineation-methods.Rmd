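---
title: "Comparing PET metabolic tumor volume delineation algorithms on synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing PET metabolic tumor volume delineation algorithms on synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtvbench)
```

## The problem

Radiation oncology increasingly uses FDG-PET to support gross tumor volume
(GTV) delineation, but the metabolic tumor volume (MTV) one obtains depends
strongly on the segmentation algorithm, on the software implementing it, and
even on apparently innocuous processing steps: resampling the PET onto the
planning-CT grid, and exporting the volume to a treatment-planning system as
a DICOM RT Structure Set. `mtvbench` reimplements this comparison as a
reproducible benchmark on synthetic PET/CT phantoms with known ground truth,
so that the qualitative findings — which arm over- or under-segments, how
conformal two arms are, which transfer conventions shrink or expand a volume
— can be verified as sign and ordering properties rather than taken on
faith from a single clinical dataset.

Clinical PET studies of this design cannot be reproduced at the desk: the
patient images are not public, and no pathology gold standard exists even in
principle. The phantom cohort therefore plays the role of the patient
population, and the pre-blur rasterized lesion plays the role of the
reference volume.

## The phantom model

A phantom case is built on a 4 mm isotropic PET grid (default
64 × 64 × 48 voxels, a reduced pelvic field of view that keeps the
benchmark fast while leaving several lesion diameters of background on every
side). Generation proceeds in the order a scanner would impose:

1. paint a uniform background SUV (default 2.0, a typical pelvic soft-tissue
   level);
2. add each ellipsoidal lesion as a plateau at its uptake value, optionally
   modulated by spatially correlated Gaussian texture (smoothed white noise
   with a given correlation length) for heterogeneous lesions, clipped at 0;
3. convolve with an isotropic Gaussian point-spread function
   (default FWHM 7 mm, the resolution class of clinical TOF PET/CT);
4. add voxelwise Gaussian noise whose standard deviation scales with the
   square root of the local mean, normalized to a given value at background
   level (default 0.15 SUV) — an approximation to the intensity-dependent
   noise of reconstructed PET, chosen because no reconstruction chain is
   being emulated;
5. clip at zero.

The ground-truth mask is the pre-blur rasterization of the lesion: a voxel
belongs to the truth iff its center satisfies the ellipsoid inequality.
Everything is deterministic given the case seed.

The default cohort draws 31 cases: lesion analytic volumes log-normal with
`meanlog = log(20)` and `sdlog = 0.85` (spanning roughly 4–120 ml, the
clinically reported MTV range for locally advanced rectal carcinoma),
tumor-to-background contrast uniform in [3, 10], mild ellipsoid anisotropy,
and half the lesions heterogeneous (texture sd 25 % of uptake). Bladder-like
confounder structures can be placed outside the analysis box to exercise the
region-restriction behavior that a physician's manual ROI placement provides
in the clinic.

What the generator does **not** emulate: sinogram-level reconstruction
artifacts, time-of-flight weighting, scatter and randoms, respiratory and
organ motion, and the full textural complexity of clinical uptake. Passing
tests on these phantoms therefore demonstrate the *mechanisms* under study
(threshold ordering, dialect effects, rasterization conventions), not
clinical performance of any arm.

## The six delineation arms

All arms operate inside an axis-aligned analysis box (the ROI) and finish by
keeping only the 26-connected component containing the hottest ROI voxel —
the automated counterpart of the physician excluding physiological uptake.

* **Absolute threshold (SUV 2.5)** — voxels with SUV ≥ 2.5. Two arms carry
  this label with different reference-uptake dialect tags for reporting
  symmetry; the dialect does not affect an absolute threshold, so their
  masks coincide by construction.
* **Relative threshold (45 %)** — voxels at or above 45 % of the reference
  uptake. The reference has two *software dialects*: `max_voxel` uses the
  hottest ROI voxel; `neighborhood_mean5` averages the hottest voxel with
  its 4 hottest 26-neighbors, reproducing workstations that threshold
  against a five-pixel average around the maximum. The five-pixel kernel is
  formalized in 3-D (the commercial description does not state whether the
  neighborhood is planar); this choice is config-free and symmetric.
* **FLAB-style fuzzy Bayesian classification** — two Gaussian intensity
  classes plus `n_fuzzy_levels = 3` transition levels at mixing fractions
  `eps = l/(L+1)`, iteratively reassigned under a local prior equal to each
  level's frequency among a voxel's 26 neighbors (uniform on the first
  sweep), with class parameters re-estimated from fuzzy-weighted
  memberships. Initialization is a deterministic two-means split started
  from the intensity extremes; the tumor class is the higher-mean class by
  convention, so label-swapped initializations converge identically. The
  mask keeps levels with `eps >= 0.5`. A variance floor of `1e-6` times the
  intensity range keeps likelihoods proper on noiseless two-valued input; a
  constant ROI is rejected as unidentifiable.
* **Gradient-based method (GBM)** — bilateral denoising (spatial sigma 6 mm,
  range sigma 1 SUV), Richardson–Lucy deconvolution against the scanner PSF
  (10 iterations by default; the iteration count of the original clinical
  implementation is not published), spacing-aware gradient magnitude,
  deterministic watershed, agglomerative merging of basin mean intensities
  into two clusters, tumor = cluster containing the hottest ROI voxel.

### Numerical choices in the watershed

Voxels are processed in ascending gradient order with ties broken by linear
(lexicographic) voxel index. A voxel with no labeled neighbor opens a basin
(regional minimum). A voxel with labeled neighbors joins the basin of the
neighbor whose *denoised intensity* is closest to its own; remaining ties go
to the neighbor with the smaller gradient, then to the lexicographically
smallest neighbor. The intensity-affinity rule is the load-bearing choice:
watershed-line voxels sit on the gradient ridge between tumor and
background, and assigning them by gradient alone lets numerically tiny
gradient differences (or deconvolution ringing) strand the outermost tumor
shell in background basins. Since the subsequent cluster step groups basins
by intensity anyway, attaching ridge voxels to the region they resemble is
the consistent completion of the method; it also makes the noiseless
two-plateau case segment exactly.

## Resampling between PET and CT spaces

Clinical viewers resample PET onto the planning-CT grid before delineation.
`resample_suv` applies a rigid transform to target voxel centers and
interpolates trilinearly (the workstation kernel is not published;
trilinear is assumed and stated as an assumption). Points outside the
source extent read 0 (background air), not an error. Masks resample by
nearest neighbor. The planning-CT grids use the two clinical
reconstructions: 0.59 × 0.59 × 3 mm ("fine", the 1024² matrix) and
1.17 × 1.17 × 3 mm ("coarse", 512²).

Two facts shape the resampling experiment:

* Trilinear interpolation is a convex combination, so the resampled maximum
  can only fall; but the `neighborhood_mean5` reference tends to *rise*,
  because on a 0.59 mm grid the five averaged pixels are essentially at the
  maximum, while on the 4 mm grid the four neighbors sit visibly below it.
* At thresholds below the blurred profile's half-height, linear
  interpolation chords overestimate the convex profile tail, inflating
  fixed-threshold volumes by a few percent independently of any dialect
  effect.

The dialect-effect experiment therefore uses *blurred-peak phantoms*:
heterogeneous, high-contrast lesions (radius 10–18 mm, contrast 6–10,
texture sd 50 % of uptake at 5 mm correlation length) whose hottest voxel is
a focal blurred peak. On homogeneous plateau lesions the five averaged
pixels are all on the plateau and the mechanism under test vanishes; a
fixture that cannot exhibit the mechanism cannot test it. With peaked
lesions the reference rises and the 45 % volume falls for the large
majority of cases, the direction reported clinically.

## Contours, dialects, and the RT Structure Set round trip

The DICOM transfer experiment models why volumes change when moved between
workstations: the exporting software draws boundaries in one convention and
the importing software re-rasterizes them in another.

* `voxel_edge` contours follow the outer voxel-box edges (staircase
  polygons) — boundaries that "follow the tumor bordering voxels".
* `voxel_center` contours pass through boundary-voxel centers (Moore
  tracing) — boundaries that cut across the frontline voxels.
* `center_inside` rasterization keeps voxels whose centers fall inside or
  on a polygon (even-odd rule; boundary counts as inside, which makes the
  edge-dialect round trip on the source grid an exact identity).
* `any_overlap` keeps voxels whose in-plane box touches the polygon at all.

Composing a shrinking export with a center rasterization systematically
reduces volume; composing an edge export with an overlap rasterization
systematically expands it — the two signs observed for the two clinical
transfer directions. The magnitude grows with lesion size and voxel size;
on the 4 mm PET grid the expansion convention adds an entire boundary-voxel
shell, which is why the benchmark asserts signs and monotonicity, never the
clinical millilitre values, which belong to that study's patients, grids,
and software versions.

Only outer boundaries are exported: per slice and per 4-connected
component, holes are dropped. The tumors modeled here are simply connected,
and the test fixtures fill in-plane holes accordingly; masks with genuine
in-plane holes would gain volume on re-rasterization. Components whose
center path has fewer than three distinct points (single voxels, 1-voxel
lines) cannot form a polygon under the center dialect; they are skipped and
counted in the contour set's `skipped` field.

The RT Structure Set writer emits explicit-VR little-endian files with the
minimal mandatory modules and 6-decimal coordinate strings (quantization
≤ 5 × 10⁻⁷ mm per coordinate); the reader handles defined- and
undefined-length sequences. No R DICOM package ships in the analysis stack,
so the codec is implemented in the package and cross-validated against an
independent Python reader in the test suite.

## Agreement statistics

* **Conformity index**: intersection over union of two masks (the Jaccard
  index). The source description divides by the "conjunction"; union is the
  only reading under which a mask agrees with itself at 1 and published
  pairwise values below 1 are possible.
* **ICC**: two-way random effects, absolute agreement, single rater —
  ICC(2,1) — computed from the two-way mean squares, with the F-based 95 %
  lower confidence limit (McGraw & Wong). The clinical report names neither
  variant nor software; ICC(2,1) with a lower limit matches its
  presentation. Perfect-agreement matrices degenerate the F interval; the
  lower limit then equals the estimate.
* **Paired tests**: two-sided paired t and Wilcoxon signed-rank with the
  standard zero-difference conventions (all-zero differences report p = 1;
  constant non-zero differences make t undefined and error).
* **Friedman test** across ≥ 3 arms, with Holm-corrected pairwise Wilcoxon
  post-hocs. The parametric ANOVA-2/Scheffé ladder is deliberately replaced
  by this self-consistent nonparametric ladder; MTV distributions are
  right-skewed and the benchmark asserts ordering, not effect sizes.
* **Bland–Altman**: mean difference, SD, and 1.96-SD limits for
  before/after volume pairs.

## Problem sizes and determinism

The default study — 31 cases, six arms, resampling of the four threshold
arms onto the fine CT grid restricted to each case's analysis box, and two
transfer scenarios per case and arm — completes in about a minute on one
CPU, and every table is byte-identical on re-run with the same seed: one
master seed drives cohort sampling, per-case noise seeds, and nothing else
is stochastic. Unit-test fixtures use small grids (≈ 20³) so the full test
suite stays fast.

## Known limitations

* Homogeneous plateaus make the two absolute-threshold arms literally
  identical (the dialect tag cannot matter for an absolute threshold), so
  their pairwise conformity is exactly 1 here, whereas distinct software
  renderings of the same threshold differ slightly in the clinic.
* The SUV 2.5 arm systematically over-segments blurred high-contrast
  lesions: at 8:1 contrast over unit background with a 7 mm PSF the
  continuum SUV ≥ 2.5 region of a 15 mm sphere is ~40 % larger than the
  sphere — the same over-segmentation the clinical comparison reports for
  this arm. Recovery-accuracy expectations in the ±25 % range are met by
  the 45 %, FLAB, and GBM arms but not by an absolute threshold under
  these conditions; this is a property of the method, not a defect of the
  implementation.
* Registration is taken as known (transforms are inputs); estimating it is
  out of scope, as are oblique grids, dose planning, and margin expansion.
* The noise level is a free parameter: the source acquisition protocol
  reports scan times but no noise figures, so 0.15 SUV at background is a
  stated choice, not a scanner match.
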