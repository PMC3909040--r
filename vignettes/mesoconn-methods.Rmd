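---
title: "Identifying dopaminergic midbrain-striatal pathways in resting-state fMRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying dopaminergic midbrain-striatal pathways in resting-state fMRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoconn)
```

## The scientific problem

Midbrain nuclei rich in dopaminergic neurons (substantia nigra, ventral
tegmental area) project densely to the striatum, but a raw resting-state
correlation between a midbrain seed and a striatal voxel is not evidence
that the connection is dopaminergic: shared physiological noise and
non-dopaminergic projections produce correlations too. The approach
implemented here identifies *putatively dopaminergic* midbrain-caudate
connections by requiring the connectivity to be jointly modulated by

1. a pharmacological challenge (a D2 agonist, bromocriptine, versus
   placebo), and
2. a dopamine-sensitive trait (working-memory span, measured by a
   listening span task and used as a proxy for baseline dopamine tone),

in the *inverted-U* pattern that characterises dopamine function: the
agonist increases connectivity in low-span (low-dopamine) individuals and
decreases it in high-span (high-dopamine) individuals.

`mesoconn` implements this whole analysis chain — preprocessing, seed-based
connectivity mapping, the inverted-U group contrast with FDR/small-volume/
cluster thresholding, and the voxel-set overlap (Venn) analysis — together
with a synthetic BOLD cohort generator with planted ground truth, so every
stage is testable end-to-end without access to raw scans.

## The statistical model

### Seed connectivity

For each subject-session run, the mean time series of the midbrain seed is
correlated with every brain voxel's series (Pearson), and the correlation
is variance-stabilised by the Fisher transformation
$z = \operatorname{atanh}(r)$. Voxels whose series have zero variance are
carried as *invalid* through every later stage rather than silently set to
zero; correlations at $|r| \ge 1$ follow an explicit clamp policy
(`clamp = TRUE` clamps to $1 - 10^{-7}$ with a warning, `clamp = FALSE`
marks the voxel invalid).

### The inverted-U interaction

The design crosses a within-subject factor (drug: placebo vs
bromocriptine) with a between-subject factor (span group: low vs high,
split at an inclusive score cutoff of 3.5). The quadratic contrast with
weights $(-0.5, 0.5, 0.5, -0.5)$ over the canonical cells (low-placebo,
low-drug, high-placebo, high-drug) is positive exactly when the drug helps
low-span and hurts high-span subjects.

Rather than choosing an ANOVA sum-of-squares convention for this mixed
design, the package computes the exact likelihood-equivalent test: per
subject the paired difference $d = z_{\text{drug}} - z_{\text{placebo}}$,
then a pooled-variance two-sample $t$ comparing $d$ between span groups on
$n_{\text{low}} + n_{\text{high}} - 2$ degrees of freedom. Under the
default weights the reported contrast estimate equals
$(\bar d_{\text{low}} - \bar d_{\text{high}})/2$, i.e. the weights applied
to the four cell means. Positive $t$ = inverted-U.

### Thresholding

Voxelwise $p$ values are corrected with the Benjamini-Hochberg step-up
procedure (independence variant, the field's default reading of "FDR
corrected"), optionally restricted to an a priori small volume (the caudate
mask), followed by a cluster-extent filter (default: components of fewer
than 20 face-connected voxels are removed; 18- and 26-neighbourhoods are
available). Invalid voxels carry no $p$ value and do not count toward the
number of tests. The loose sets used by the overlap analysis are
uncorrected $p < 0.05$ with a positive sign restriction.

### Span correlations and their comparison

Over the surviving inverted-U voxels, each subject's mean $z$ is
correlated with the span score separately per condition
($t = r\sqrt{n-2}/\sqrt{1-r^2}$, two-tailed). The placebo and drug
correlations are compared with the independent-samples Fisher test
$Z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2)/
\sqrt{1/(n_1-3) + 1/(n_2-3)}$. Two-tailed $p$ values are the default
throughout; with $r_1 = 0.66$, $r_2 = -0.69$ and $n_1 = n_2 = 16$ this
formula gives $Z = 4.183$.

### Overlap (Venn) analysis

Thresholded voxel sets are compared by exact set arithmetic. The headline
quantity is the percentage of reference-set voxels inside the
intersection, rounded half away from zero to an integer (so 122/955 → 13%,
61/122 → 50%, 4/28 → 14%). The caudate is split into head/body versus tail
at a coronal plane (world $y = 2$ mm by default; a voxel is head/body iff
its world $y$ is strictly greater than the boundary, so boundary voxels go
to the tail). Regional overlap proportions are compared with a Pearson
chi-square on the 2×2 (overlap, non-overlap) table, without continuity
correction by default (a Yates flag is available).

## The synthetic cohort generator

No raw scans ship with this package; the generator produces seeded,
fully reproducible cohorts that emulate the study conditions:

* 16 subjects (8 low-span, 8 high-span), each with a placebo and a drug
  session in counterbalanced order; span scores uniform on 1.5–3.4 (low)
  and 3.5–5.5 (high) — only the 3.5 cutoff is dictated by the design, the
  score ranges are this package's choice of a plausible spread;
* 150 timepoints at TR = 2 s (five minutes of resting data);
* a labelled phantom with anisotropic 1.8 × 1.8 × 3.45 mm voxels: midbrain
  seed, caudate head/body and tail (separated exactly at the world-y
  split), putamen, ventral striatum, white-matter and CSF slabs, generic
  brain tissue, and empty background.

Every voxel series is the linear mixture
$x(t) = a\,s(t) + b\,c(t) + \varepsilon(t)$ of a band-limited seed signal
$s$, a band-limited run-wide physiological confound $c$ (carried at unit
weight by the white-matter and CSF regions, weight `confound_weight` = 0.3
by default in gray matter), and white Gaussian noise. Band-limited signals
are generated by FFT masking of white noise on the 0.009–0.08 Hz band and
renormalised — exact spectral control with no filter transients. Because
the components are independent, the population seed correlation has the
closed form $r = a\sigma_s/\sqrt{a^2\sigma_s^2 + b^2\sigma_c^2 +
\sigma_e^2}$ (`planted_correlation()`), which the generator inverts to
plant any target $r$; unreachable targets (no non-seed variance) raise an
error naming the offending design cell.

Caudate voxels are partitioned into three ground-truth classes: a
connected block of `dopaminergic_invertedU` voxels (15% of the caudate by
default) whose planted correlation follows the cell pattern
$(0.1, 0.5, 0.5, 0.1)$; a connected block of `connected_constant` voxels
(45%, $r = 0.5$ in every cell) standing for real but non-dopaminergic
connectivity; and `null` voxels. Both blocks are grown as connected
regions (seeded breadth-first growth) because the cluster-extent threshold
would, by design, remove scattered single-voxel effects. The class map,
effect specification and seed are recorded in a ground-truth manifest that
serialises to JSON alongside the NIfTI volumes, so recovery metrics never
depend on in-memory state.

Randomness is fully seeded: every subject-session draws from a child
stream derived by stable hashing of the subject and session identifiers,
so any subset of runs is reproducible independently of generation order,
and identical inputs give bit-identical volumes.

What the generator does *not* emulate: hemodynamic response convolution,
head motion, scanner drift and spike artifacts, physiological noise
spectra (cardiac/respiratory aliasing), spatial autocorrelation of noise,
and anatomical variability. Passing recovery tests on this phantom shows
the statistical chain is correct and calibrated, not that the pipeline is
robust to real-data artifacts those mechanisms produce.

## Preprocessing: choices and numerics

The canonical stage order is band-pass filter → spatial smoothing →
nuisance regression, with the white-matter and CSF mean series extracted
from the already filtered and smoothed data (whether the original analysis
filtered its nuisance series is not stated anywhere; extracting them after
filtering keeps regressor and data spectra matched).

* **Temporal filter.** Per-voxel mean and linear trend are removed, then a
  second-order Butterworth band-pass (0.009–0.08 Hz) is applied with zero
  phase. The zero-phase (forward-backward) cascade of a filter $H$ has the
  real transfer function $|H|^2$; the package applies that
  magnitude-squared response spectrally, after odd-reflection padding of
  each series, and materialises the whole detrend+filter chain once as an
  $n_t \times n_t$ matrix so filtering a cohort is a handful of BLAS
  products. An in-band 0.04 Hz sinusoid passes with amplitude within 1%;
  a 0.2 Hz sinusoid is attenuated by more than 99%. The filter is exactly
  linear, which the test suite asserts directly.
* **Smoothing.** Separable 3D Gaussian convolution with per-axis
  $\sigma_{\text{vox}} = \text{FWHM} / (\text{voxel size} \cdot
  2\sqrt{2\ln 2})$, so anisotropic voxels are handled correctly; kernels
  are truncated at $4\sigma$ and renormalised; volume edges are reflected.
  FWHM 0 is the exact identity.
* **Nuisance regression.** Ordinary least squares per voxel on the
  confound columns plus an intercept; residuals are orthogonal to every
  confound to near machine precision. A rank-deficient confound matrix is
  an error naming the collinear columns.

Note one consequence of the generative model: nuisance regression removes
the shared confound and band-pass filtering removes out-of-band noise, so
the correlations measured *after* preprocessing are systematically larger
than the planted raw-series values. The planted $r$ is the population
correlation of the generated series; closed-form recovery checks therefore
correlate raw runs, while the group-level analyses only require the cell
*pattern* (equal cells stay equal under preprocessing; the inverted-U
ordering is preserved).

## Calibration and recovery studies

Three simulation studies back the package's claims; all run at the study
conditions (16 subjects × 2 sessions, 150 timepoints) on the default
20 × 24 × 10 phantom (288 caudate voxels), with seeds fixed by the caller:

* **Closed-form recovery.** With every caudate voxel planted at
  $r = 0.6$, the mean voxelwise Fisher $z$ over 200 seeded replicates is
  within ±0.03 of $\operatorname{atanh}(0.6) = 0.69315$ (a compact
  10 × 16 × 6 phantom keeps this Monte Carlo fast; the planted correlation
  does not depend on grid size).
* **Type-I calibration.** Under a null effect (all four cells planted at
  the same correlation), the uncorrected voxelwise rejection rate of the
  interaction contrast at $p < 0.05$, pooled over 20 replicate cohorts
  (≥ 2000 caudate voxels), lies inside the binomial 99% interval, and the
  FDR-corrected small-volume inverted-U set is empty in at least 18 of 20
  replicates.
* **Parameter recovery.** With the default inverted-U effect, the
  pipeline's corrected inverted-U set recovers planted dopaminergic voxels
  with mean sensitivity ≥ 0.8 and ≤ 5% false positives among non-planted
  caudate voxels over 20 seeds, and the recovered voxels show the expected
  cell pattern (drug raises connectivity in low-span subjects, lowers it
  in high-span subjects).

Two design choices matter for these studies. First, they run with
`fwhm_mm = 0`: smoothing makes neighbouring voxels dependent (invalidating
the binomial reference for a pooled rejection rate) and smears planted
signal into adjacent null voxels, which the voxel-level ground truth would
then count as false positives (~18% apparent false-positive rate with 4 mm
smoothing, ~0.4% without, at unchanged sensitivity). The default pipeline
keeps the 4 mm kernel; the calibration simply measures the statistics on
the scale at which ground truth is defined. Second, the replicate counts
(200 / 20 / 20) and phantom sizes are the package's chosen problem sizes;
they give Monte-Carlo standard errors comfortably below the tolerances
being asserted.

## Degenerate inputs and tie-breaking

* Zero-variance voxel series: invalid, never zero (`seed_connectivity_map`).
* Zero between-map variance in a group test: the voxel is flagged invalid
  with a warning, never $t = \infty$.
* BH with no rejections returns an empty set and an `NA` threshold.
* Perfect span correlation ($|r| = 1$): $p$ is reported at the smallest
  positive double rather than 0 or NaN.
* Percentage rounding is half away from zero (122/955 → 13, 4/28 → 14),
  not banker's rounding.
* Caudate voxels exactly on the coronal boundary belong to the tail (the
  head/body is *strictly* anterior); the boundary is configurable.
* The chi-square errors on a zero marginal rather than returning NaN.

## Known limitations

* The group one-sample connectivity map treats the 32 session maps as
  independent observations, mirroring the original analysis; the two maps
  of one subject are in fact dependent. The interaction contrast is immune
  (it works on within-subject differences).
* The BH procedure assumes independence (or PRD) across voxels; under the
  4 mm kernel neighbouring tests are positively dependent, which BH
  tolerates but the package does not attempt to model.
* No mixed-effects or permutation inference; no covariates beyond drug and
  span; no partial correlations.
* The generator's simplifications (previous section) mean real-data
  robustness — motion, physiology, registration error — is out of scope.

## Reproducibility contract

`run_pipeline()` consumes a single validated `run_config()` carrying every
tunable (band, FWHM, contrast weights, q, cluster extent and connectivity,
split coordinate, span cutoff, seed) and echoes it into every output
directory (`config.json`), alongside the machine-readable `report.json`,
a text report, and the thresholded voxel sets as NIfTI masks with TSV
index lists and JSON provenance. Identical configurations produce
byte-identical reports.
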