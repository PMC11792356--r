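# thighfat

Quantification of thigh muscle fat infiltration from T1-weighted MRI, with
the two-group statistics used in cross-sectional muscle-quality studies and
a synthetic phantom testbed.

## What it does

On T1-weighted MR images fat is bright and muscle is dark. Given a mid-thigh
volume and a co-registered label map (fascia, 13 muscle compartments,
femur), the package measures two fat pools over the 10 middle slices (a
30 mm region of interest):

* **intraMAT** — intramuscular adipose tissue, inside the muscle
  compartments;
* **interMAT** — intermuscular adipose tissue, between muscles and beneath
  the fascia.

The measurement chain is: slice-wise non-local-means denoising →
multiplicative bias-field correction → intensity normalization to [0, 255] →
automatic derivation of intraMAT/interMAT/fascia region masks from the
labels → locally adaptive fat segmentation, where each pixel is compared
against the Gaussian-weighted mean of its 55-pixel local neighbourhood →
volumetry in cm³, raw and normalized by the fascia-interior volume.

The statistics half compares an affected and an unaffected group per
outcome: pooled-variance independent t-test, mean difference with 95% CI,
Cohen's d on the equal-n pooled SD

```
d = |m1 - m2| / sqrt((s1^2 + s2^2) / 2),
```

Kolmogorov–Smirnov + skewness normality screening, and an a-priori sample
size from the two-sample noncentral-t power function. It accepts either raw
columns or printed summary statistics (mean, SD, n) — both routes agree
exactly.

Because no public dataset accompanies this study design, the package ships
a seeded synthetic thigh phantom (`generate_phantom()`, `generate_cohort()`)
with known ground-truth fat volumes; all validation is phantom-based.

## Worked example

Feeding the published group summaries (n = 23 per group) of a BMI-matched
knee-osteoarthritis comparison through the statistics module:

```r
library(thighfat)
tab <- compare_table(koa_reference_table(),
                     group_order = c("affected", "unaffected"))
tab[, c("outcome", "mean_difference", "ci_low", "ci_high",
        "p_value", "cohens_d")]
#>                 outcome mean_difference  ci_low ci_high  p_value cohens_d
#> 3            womac_pain             7.9   6.508   9.292 9.15e-15   3.3716
#> 9             torque_nm           -22.6 -47.136   1.936 7.01e-02   0.5474
#> 10         intermat_cm3             3.0  -3.095   9.095 3.27e-01   0.2925
#> 11         intramat_cm3             3.7   1.135   6.265 5.69e-03   0.8573
#> (7 further rows)
```

The affected group carries 3.7 cm³ more intraMAT (95% CI 1.1–6.3,
p = 0.0057, d = 0.86) while interMAT does not differ (p = 0.33) — the
mean-difference sign convention is affected minus unaffected. The design's
sample size reproduces from the power calculation:

```r
required_sample_size(power_spec(alpha = 0.05, power = 0.80,
                                min_difference = 3.0, sd = 3.5))
#> [1] 23
```

And a full phantom-cohort run, from simulation through segmentation to the
group comparison:

```r
res <- run_pipeline(list(phantom = list(profile = "test", n_per_group = 6),
                         seed = 1), "out/")
res$comparisons[res$comparisons$outcome == "intramat_cm3", ]
```

which writes `volumes.csv` (per-subject fat volumes), `comparison.csv`, and
a `manifest.json` with checksums; identical configuration + seed reproduces
the CSVs byte for byte.

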