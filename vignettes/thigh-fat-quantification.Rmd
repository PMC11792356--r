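---
title: "Quantifying thigh muscle fat infiltration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thigh muscle fat infiltration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thighfat)
```

## The measurement problem

On T1-weighted MR images of the mid-thigh, adipose tissue is hyperintense
relative to muscle. Fat infiltration of the thigh musculature comes in two
anatomically distinct pools: **intramuscular** adipose tissue (intraMAT),
scattered within the muscle bellies, and **intermuscular** adipose tissue
(interMAT), lying between muscles and beneath the muscular fascia.
Cross-sectional studies of knee osteoarthritis compare these volumes between
an affected and an unaffected group, so the pipeline has two halves: an
image-analysis half that turns a volume plus a manual muscle/bone/fascia
segmentation into per-subject fat volumes, and a statistics half that
compares the groups.

`thighfat` implements both halves, plus a synthetic phantom generator. No
public MRI dataset accompanies the study design this package serves, so
validation runs entirely on phantoms with known ground truth: every claim a
test makes is a claim about recovery of a constructed truth, not about
agreement with any particular scanner.

## Image-analysis pipeline

All image operations run **slice by slice** — with 3 mm slices and 1 mm
pixels the through-plane resolution is too coarse for meaningful 3-D
neighbourhoods.

1. **Non-local-means denoising** (`nlm_denoise()`). Each pixel becomes the
   similarity-weighted average of its search window, with weights
   `exp(-d2/h2)` where `d2` is the mean squared difference between the two
   local patches. Defaults: patch radius 1 (3 x 3 patches), search radius 5
   (11 x 11 window), and `h = 0.8` times the slice's noise SD estimated by
   the pseudo-residual method. The self weight is set to the maximum
   neighbour weight, the usual guard against self-domination. These
   parameters are conventional choices; nothing in the pipeline is sensitive
   to them at the tested noise levels.
2. **Bias-field correction** (`correct_bias()`). MR coil shading is modelled
   as a smooth multiplicative field. The default estimator fits a total
   degree-2 polynomial surface to the log-intensities inside the body mask
   by iteratively reweighted least squares (bisquare weights, 3 iterations,
   which damps the pull of genuine anatomy on the fit), exponentiates the
   fitted surface (so the field is strictly positive), divides it out, and
   rescales so the mean intensity inside the mask is preserved exactly. A
   Gaussian-smoothed-surface mode and a `corrector` function argument
   provide a seam for plugging in an external N4-style implementation. A
   deliberate limitation: a low-order polynomial can absorb genuinely smooth
   anatomical trends as well as coil shading; because the downstream
   threshold is local, this has no measurable effect on fat recovery in the
   tested settings.
3. **Intensity normalization** (`normalize_intensity()`). Affine map of the
   volume's global min/max to `[0, 255]` (`strict_minmax`), with a
   percentile-clipping variant for data with hot pixels. Per-volume scope is
   the default; per-slice is available by configuration.

### Region masks

`derive_regions()` consumes only label codes: muscles (codes 10–22) form the
intraMAT ROI; the fascia-interior space that is neither muscle nor femur
(code 2) forms the interMAT ROI; the femur — including its bright,
fat-like marrow — is excluded from both; subcutaneous fat and background
never enter any ROI. The fascia-interior union of all three is the
normalizing volume. Two edge rules are worth stating: voxels on the fascia
line itself belong to no ROI, and a label map whose muscles tile the whole
interior (no code-2 voxels) is legal and simply has an empty interMAT ROI.
When code-2 voxels are present, any muscle voxel touching background or
subcutaneous fat in-plane is treated as evidence of a malformed map and
rejected with the offending codes named.

### Adaptive fat segmentation

`adaptive_threshold()` computes, per pixel, the Gaussian-weighted mean of
its `block_size_px` square neighbourhood (default 55 px, the window size
that matched expert visual segmentation of 512 px mid-thigh slices) plus an
`offset`; a pixel is fat iff its intensity strictly exceeds that threshold.
Numerical choices:

* Gaussian sigma defaults to `(block - 1)/6` (support ~ ±3 sigma). The
  window size is documented; the weighting sigma is a convention, exposed as
  a parameter.
* Borders are handled by symmetric reflection; blocks up to
  `2 * min(dim) - 1` are legal.
* "Strictly exceeds" is applied with a `1e-9`-relative guard so that exactly
  homogeneous regions never threshold on convolution round-off.
* The threshold field is computed on the **full slice** and then intersected
  with each ROI; fat segmentation is therefore identical across ROIs.
* With `offset = 0`, symmetric noise in a homogeneous region puts roughly
  half of its pixels above the local mean. On noisy data the offset must be
  positive; `calibrate_offset()` picks it by maximizing voxelwise F1 against
  a calibration phantom's ground truth, mirroring how a window would be
  tuned against an expert's reference on real data. On noise-free images the
  default 0 is exact.

`select_middle_slices()` fixes the measured region: the 10 middle slices of
the 24-slice stack, a 30 mm region of interest, with the lower-start
tie-break `floor((n_total - n_keep)/2)` (returned 1-based). Volumes are
voxel counts times voxel volume (cm³), reported both raw and normalized by
the fascia-interior volume over the same slices.

## The phantom

`phantom_spec()` + `generate_phantom()` build a cylindrical thigh: a fascia
disc (default radius 80 mm in the 512 x 512 / 1 mm full profile) containing
an off-centre femur (dark cortical shell, bright marrow) and 13 muscle
compartments formed by a seeded angular partition, separated by ~2 px
seams and a thin subfascial layer (code 2); a subcutaneous fat ring
surrounds the fascia. IntraMAT is placed as random speckle clusters (radius
1–3 px) inside muscle compartments until the requested fraction of muscle
voxels is fat; interMAT as clusters filling the requested fraction of the
seam space. Corruption follows the magnitude-MRI model: a random in-plane
degree-2 polynomial bias field scaled to `1 ± bias_amplitude` (default
0.2), then Rician noise (default sigma 5 against muscle ~90, SNR ≈ 18).
Identical spec + seed is bit-identical by construction.

Default tissue intensities (arbitrary T1-like units): fat 200, muscle 90,
cortical bone 30, marrow 190, background 10.

What the phantom does **not** emulate: real muscle shapes, partial-volume
blur at tissue interfaces, chemical-shift artefacts, inter-subject anatomy
variation, or any empirically estimated intraMAT morphology — speckle size
and seam width are free knobs, not estimates. Passing recovery tests on
phantoms therefore demonstrates internal consistency of the measurement
chain, not clinical accuracy.

`generate_cohort()` draws per-subject target intraMAT volumes from
zero-truncated normals (defaults 9.9 ± 5.0 vs 6.2 ± 3.5 cm³ for the
affected/unaffected groups, n = 23 each — the reference study conditions),
then solves for the speckle fraction that realizes each target given that
subject's muscle capacity, erroring if a draw exceeds capacity. Truncation
at zero shifts the realized group means slightly upward; tests account for
this. Ground-truth volumes are whole-volume mask volumes; recovery
comparisons restrict the stored truth masks to the measured slice range.

## Statistics

The statistics half operates on raw columns or printed summary statistics
(mean, SD, n) interchangeably — the two routes agree to machine precision
because the pooled t-test and Cohen's d are functions of the sufficient
statistics only.

* `pooled_t_test()`: Student's pooled-variance two-sided t (Welch by flag).
  "Independent t-test" is read as the pooled form: equal group sizes and a
  pooled-SD power calculation point that way.
* `cohens_d()`: `|m1 - m2| / sqrt((s1² + s2²)/2)`, the equal-n pooled form.
  Feeding the published summary table through this formula reproduces 10 of
  11 printed effect sizes at two decimals; the intraMAT row prints 0.83
  where the rounded summaries determine 0.857 — the published value was
  evidently computed on unrounded data, and the package reports what the
  rounded inputs determine rather than reverse-engineering the source.
* `normality_screen()`: Lilliefors-corrected KS test plus adjusted
  Fisher–Pearson skewness; "normal" is decided by the ±1 skewness window,
  with the KS p reported but not gating (for n of 3–4, where the Lilliefors
  test is undefined, a plain KS test against the fitted normal is
  substituted).
* `required_sample_size()`: smallest per-group n whose two-sided noncentral-t
  power reaches the target; at alpha 0.05, power 0.80, difference 3.0 cm³,
  SD 3.5 cm³ it returns 23 per group, and it is cross-checked against
  `stats::power.t.test` in the tests.
* No multiple-testing correction is applied — each outcome is tested at
  0.05, matching the design this reproduces.

## Orchestration and reproducibility

`run_pipeline()` takes a validated configuration (list or YAML; unknown keys
are an error), generates the cohort, optionally calibrates the threshold
offset on a held-out phantom, quantifies every subject, and writes
`volumes.csv`, `comparison.csv`, and a `manifest.json` carrying the
configuration, package version, and MD5 checksums of the outputs. All
randomness descends from the single configuration seed; re-running a
configuration reproduces the CSVs byte for byte.

## Problem sizes used in validation

Unit tests run on a miniature 64 x 64 x 8 thigh (24 mm fascia); recovery and
cohort experiments run on the reduced `"test"` profile — 128 x 128 x 24 at
1 mm pixels with a 40 mm fascia, i.e. the acquisition geometry at half the
thigh scale — which preserves every topological property the pipeline
depends on while keeping a full 23-vs-23 cohort replicate under half a
minute. The full 512-profile defaults exist for realistic-scale runs.

A known statistical caveat: with the reference effect size (difference
3.7 cm³ against SDs 5.0/3.5) the per-replicate power of the end-to-end
cohort experiment is in the mid-0.8s, so demanding near-universal
significance across a small number of replicates sits close to the margin;
the replicate experiment (`replicate_cohort_experiment()`) reports
per-replicate p-values so this can be inspected directly.

## Known limitations

* The bias corrector is a deliberate low-order surrogate for the full
  B-spline N4 hierarchy; the `corrector` seam exists for swapping in an ITK
  implementation where available.
* The phantom's morphology knobs are unvalidated against real intraMAT
  texture; absolute volume-recovery error on real scans cannot be inferred
  from phantom results.
* Whole-thigh aggregates only — no per-muscle breakdown, no Dixon-style fat
  fraction, no DICOM ingestion, no registration.
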