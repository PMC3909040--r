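# mesoconn

Seed-based resting-state fMRI connectivity analysis for identifying
putatively **dopaminergic midbrain–striatal pathways**, with a synthetic
BOLD phantom for end-to-end validation.

## The problem and who this is for

Midbrain dopaminergic nuclei (substantia nigra, ventral tegmental area)
project densely to the caudate, but a resting-state correlation between a
midbrain seed and a caudate voxel is not by itself evidence of a
dopaminergic connection — shared physiology and non-dopaminergic
projections correlate too. `mesoconn` implements an analysis that
identifies dopaminergic candidates as those voxels whose midbrain
connectivity is jointly modulated by a dopamine agonist (bromocriptine vs
placebo, within subject) and by working-memory span (a proxy for baseline
dopamine tone, between subjects) in the **inverted-U** pattern: the drug
raises connectivity in low-span individuals and lowers it in high-span
individuals.

It is aimed at cognitive-neuroscience / pharmacological-fMRI researchers
who want a reproducible, fully tested reference implementation of this
pipeline, and at methodologists who want a seeded phantom with planted
ground truth to calibrate it against.

## What it computes

For each subject-session 4D BOLD run, after band-pass filtering
(0.009–0.08 Hz, zero-phase Butterworth), 4 mm FWHM Gaussian smoothing
(anisotropy-aware) and white-matter/CSF nuisance regression, the package
forms the seed-based Fisher-z connectivity map
`z(v) = atanh(cor(seed mean series, voxel series))`. Group inference then
computes:

* the overall connectivity **one-sample t map** across all session maps;
* the **drug × span inverted-U contrast**: per subject
  `d = z(drug) − z(placebo)`, compared between span groups with a
  pooled-variance two-sample t (`df = n_low + n_high − 2`), equivalent to
  the quadratic contrast `(−0.5, 0.5, 0.5, −0.5)` over the cell means
  (low-placebo, low-drug, high-placebo, high-drug);
* **Benjamini–Hochberg FDR** at q = 0.05 with small-volume restriction to
  the caudate and a 20-voxel cluster-extent filter;
* **span–connectivity correlations** per condition and their comparison
  with the Fisher test
  `Z = (atanh r₁ − atanh r₂) / √(1/(n₁−3) + 1/(n₂−3))`;
* **Venn overlap** between thresholded voxel sets (integer percentages,
  half-away-from-zero rounding), the caudate **head/body vs tail split**
  at a coronal plane (world y = 2 mm), and a **chi-square** comparison of
  regional overlap proportions.

The synthetic cohort generator plants voxels whose population seed
correlation follows a chosen value per design cell (closed form
`r = a·σs / √(a²σs² + b²σc² + σe²)` for the mixture
`voxel = a·seed + b·confound + noise`), records the ground truth in a
JSON manifest, and is fully seeded: identical inputs give bit-identical
volumes.

## Worked example

```r
library(mesoconn)

cfg <- run_config(rng_seed = 42)   # 16 subjects x 2 sessions, 150 tp, TR 2 s
rep <- run_pipeline(cfg)
print(rep)
```

```
<mesoconn_report>
  group t map: 3942 valid voxels, max t = 108.48
  voxel sets: connectivity 277 | invertedU (svc) 88 | invertedU (p<0.05) 107 | span 83
  overlap conn vs inverted-U: 104/277 voxels (38%)
  span correlation: placebo r = 0.912 (p = 8.362e-07), drug r = -0.918 (p = 5.169e-07), Z = 7.957
  recovery: sensitivity 1.000, false-positive rate 0.184
```

Reading this: 277 caudate voxels show significant midbrain connectivity
overall (FDR + small volume + cluster filter), 88 survive the corrected
inverted-U contrast, and only 38% of the connectivity voxels overlap the
loosely-thresholded inverted-U set — connectivity strength alone does not
identify the drug-and-trait-sensitive subset. The per-subject mean z over
the inverted-U voxels correlates **positively** with span under placebo
and **negatively** under the drug, the signature of the inverted-U; the
two correlations differ at Z = 7.96. All planted dopaminergic voxels were
recovered; the 18% apparent false-positive rate here is signal smeared
into neighbouring null voxels by the 4 mm kernel (it drops to ~0.4% with
`fwhm_mm = 0`; see the methods vignette).

```r
rep$cell_means
#> # A tibble: 4 x 4
#>   cell         mean_z     se     n
#> 1 low_placebo   0.362 0.0146     8
#> 2 low_drug      1.16  0.0180     8
#> 3 high_placebo  1.15  0.0212     8
#> 4 high_drug     0.344 0.0185     8
plot_cell_means(rep$cell_means)            # the inverted-U, as a figure
plot_span_scatter(rep$span_correlations$values)
```

Every result type has `tidy()` / `glance()` methods and `autoplot()` /
`plot_*()` figures; stages are individually callable
(`simulate_cohort()`, `bandpass_filter()`, `seed_connectivity_map()`,
`interaction_contrast_map()`, `small_volume_threshold()`,
`overlap_counts()`, `split_caudate()`, `chi_square_overlap()`, ...) and
compose with `write_cohort()` / `read_cohort()` for on-disk NIfTI + TSV +
JSON round trips.

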