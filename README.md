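# mtvbench

Benchmarking PET metabolic tumor volume (MTV) delineation algorithms on
synthetic PET/CT phantoms.

## What this is for

When FDG-PET is used to support gross tumor volume delineation in
radiotherapy planning, the resulting metabolic tumor volume depends on the
segmentation algorithm, on the software dialect implementing it, on whether
the PET was resampled onto the planning-CT grid first, and on the contour
conventions used when the volume is transferred between workstations as a
DICOM RT Structure Set. `mtvbench` makes those effects measurable: it
generates synthetic phantom cohorts with known ground-truth lesions, runs
six delineation arms on them, and quantifies agreement and transfer effects
with the field's standard statistics. It is aimed at medical physicists and
methodologists who want the qualitative findings of clinical delineation
comparisons reproduced as testable sign and ordering properties.

## The methods at its core

Six delineation arms, all restricted to an analysis box (ROI) and reduced to
the 26-connected component containing the hottest ROI voxel:

| Arm | Rule |
|---|---|
| OA2.5 / PH2.5 | absolute threshold, SUV ≥ 2.5 |
| OA45% | SUV ≥ 0.45 · max voxel in ROI |
| PH45% | SUV ≥ 0.45 · mean of hottest voxel and its 4 hottest 26-neighbors |
| FLAB | two Gaussian classes + 3 fuzzy levels, locally adaptive priors from 26-neighbor label frequencies |
| GBM | bilateral denoise → Richardson–Lucy deconvolution → watershed of the gradient magnitude → 2-cluster basin grouping |

Agreement is measured by the conformity index CI(A,B) = |A∩B| / |A∪B|
(Jaccard), by ICC(2,1) (two-way random effects, absolute agreement, single
rater) with its F-based 95 % lower confidence limit, by paired t/Wilcoxon
and Friedman tests (Holm-corrected Wilcoxon post-hocs), and by Bland–Altman
statistics for before/after transfer volumes. Contour round trips compose a
boundary dialect at export (`voxel_edge` staircase polygons or
`voxel_center` paths through boundary-voxel centers) with a rasterization
rule at import (`center_inside` or `any_overlap`).

## Worked example

```r
library(mtvbench)

# a blurred 15 mm sphere at 8:1 contrast, 7 mm PSF, no noise
g <- image_grid(c(32, 32, 32), c(4, 4, 4))
les <- lesion_spec(center = c(62, 62, 62), semiaxes = c(15, 15, 15), uptake = 8)
case <- generate_phantom(phantom_spec(list(les), pet_grid = g,
                                      background_suv = 1, psf_fwhm = 7,
                                      noise_sd_at_background = 0, seed = 3))
mask_volume_ml(case$truth)
#> [1] 13.312

for (cfg in default_arms(psf_fwhm = 7)) print(run_segmentation(case$pet, case$roi, cfg))
#> <segmentation_result> OA2.5: 17.92 ml, SUVmax 8.00, SUVmean 5.54
#> <segmentation_result> PH2.5: 17.92 ml, SUVmax 8.00, SUVmean 5.54
#> <segmentation_result> OA45%: 13.31 ml, SUVmax 8.00, SUVmean 6.36
#> <segmentation_result> PH45%: 13.31 ml, SUVmax 8.00, SUVmean 6.36
#> <segmentation_result> FLAB: 13.31 ml, SUVmax 8.00, SUVmean 6.36
#> <segmentation_result> GBM: 13.31 ml, SUVmax 8.00, SUVmean 6.36
```

The analytic sphere volume is 14.14 ml and its 4 mm rasterization 13.31 ml.
The 45 %, FLAB, and GBM arms recover the rasterized truth; the absolute
SUV 2.5 threshold over-segments the blurred lesion (+27 % here) — the
systematic over-segmentation of absolute thresholds on high-contrast
lesions, visible by construction.

The full study runs all three experiments on a 31-case cohort:

```r
report <- run_study(study_config(n = 31, seed = 1))
print(report)
#> <comparison_report> 31 cases, 6 arms
#>   overall ICC(2,1) 0.857 (95% lower 0.681); Friedman p 1.98e-24
#>   transfer voxel_center+center_inside: mean delta -0.017 ml (SD 0.038)
#>   transfer voxel_edge+any_overlap: mean delta +20.164 ml (SD 11.312)
write_report(report, "report")
```

The per-arm mean volumes in that run are OA2.5/PH2.5 45.5 ml, OA45% 24.4 ml,
PH45% 25.0 ml, FLAB 25.0 ml, GBM 24.3 ml against a mean truth volume of
25.0 ml: the absolute-threshold arms are the systematic outlier, and the
transfer scenarios shrink (center dialect re-rasterized by centers) or
expand (edge dialect re-rasterized by overlap) every volume with the
expected sign. `write_report()` emits the per-case volume table, the
21-row pairwise conformity-index summary (6 truth pairs + 15 arm pairs),
the ICC table, post-hoc tests, resampling and transfer tables, and a JSON
run manifest; re-running the same configuration reproduces the CSVs
byte-identically.

A thin command-line front end is installed with the package
(`inst/cli/mtvbench.R`) with `generate`, `run-all`, `segment`, and
`roundtrip` subcommands over NIfTI volumes and RT Structure Sets.

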