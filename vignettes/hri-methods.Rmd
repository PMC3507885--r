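---
title: "Hemodynamic response imaging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemodynamic response imaging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hri)
```

## The measurement

Hemodynamic response imaging (HRI) probes cerebral vessel function with two
breathing challenges acquired as separate BOLD fMRI runs:

* **Hyperoxia** (carbogen, 95% O2 + 5% CO2) raises arterial oxygenation.
  Every perfused vessel — mature or immature — carries the extra oxygen, so
  functional vasculature of any kind responds with a BOLD signal increase.
* **Hypercapnia** (95% air + 5% CO2) triggers vasodilation, which requires
  smooth-muscle-coated, *mature* vessels. Immature, angiogenic vessels — the
  kind that high-grade tumors recruit — cannot dilate and stay silent.

The divergence between the two responses is therefore a noninvasive marker
of vessel maturity. The package turns the paired runs into three artifacts:
percent-signal-change maps per challenge, a vascular reactivity *mismatch*
(VRM) map that contrasts them on a common z-scale, and per-VOI summaries
including a vascular reactivity index.

## Block paradigms and regressors

The built-in paradigms are block designs bracketed by room air: hypercapnia
60/90/120/90/60 s (7 min) and hyperoxia 60/60/90/60/60 s (5.5 min), both at
TR = 5 s (84 and 66 volumes). Block durations must be integer multiples of
the TR; a volume belongs to the block containing its start time, a
deterministic convention that makes the gas/air segments an exact partition
of the run.

The BOLD response trails the inhaled gas by roughly one circulation time.
We model this as a configurable integer **lag** (default 1 volume = 5 s)
applied both to the boxcar regressor and to plateau extraction. Lag 0 keeps
a noiseless phantom exactly recoverable, which the exactness tests exploit.
Whether volumes at block transitions should additionally be discarded is
exposed as `discard_transition` (default 0), since standard practice varies.

## Percent signal change

Detection and estimation are deliberately decoupled:

* **Detection** correlates each voxel's full time series with the
  lag-shifted boxcar and converts Pearson's *r* to a p-value via the
  t-transform with *n* − 2 degrees of freedom. The test is two-sided by
  default so that *negative* responses — the vascular steal effect seen
  distant from some recurrent tumors under carbogen — survive masking
  (`test_sided = "one"` and a linear `detrend` are available as options).
  Thresholding is at uncorrected p < 0.05, mirroring the original analysis;
  no multiple-testing correction is applied, and this is a fidelity choice,
  not an oversight.
* **Estimation** uses only the *first* gas block against its immediately
  preceding baseline: ΔS = 100 · (S̄_gas − S̄_base) / S̄_base, with `lag`
  volumes dropped at each block onset. Repeated challenges provoke
  physiological adaptation that attenuates later blocks; restricting the
  estimate to the first block avoids that bias while detection still uses
  all the data. The phantom's `adaptation` parameter (attenuation of
  later-block amplitudes, 0.8 when enabled) exists precisely to demonstrate
  this: with adaptation < 1 an all-blocks estimate is biased low while the
  first-block estimate is unchanged.

## Normalization and the VRM map

Each challenge map is z-normalized against a reference region:
z(x) = (ΔS(x) − µ)/σ, with µ and σ the mean and unbiased SD of the defined
ΔS values in the reference — pooled GM + WM of both hemispheres in healthy
subjects, the lesion-contralateral hemisphere (split at the grid
mid-sagittal plane) in patients. The VRM map is the voxelwise difference
z_O2 − z_CO2; it is antisymmetric under swapping its inputs and identically
zero for a map against itself, which the tests assert bit-exactly.

Three genuinely open choices are exposed as configuration, with these
defaults:

* `reference_on_significant_only` (in effect, always): normalization
  statistics are computed over significant voxels only, because the maps are
  defined only there.
* Pooled vs per-tissue reference: the healthy reference pools GM and WM into
  one distribution (per-tissue statistics remain available through
  `reference_stats` on tissue masks).
* `co2_missing`: a voxel significant under O2 but silent under CO2 — the
  immature-vessel signature itself — has no z_CO2 in a masked map. The
  default leaves VRM undefined there; `"reference_min"` substitutes the
  minimum z_CO2 observed in the reference region, a conservative floor for
  an absent response. Tumor reactivity indices on masked maps require this
  mode, otherwise the headline phenomenon disappears from the map; healthy
  cohort aggregation uses the default.

Abnormality is declared by a strict threshold VRM > mean + 2 SD of the
healthy cohort's tissue reference — WM for glial lesions, GM for meningioma
(which has no glial reference tissue). Strict inequality makes the boundary
case deterministic.

## VOIs, the reactivity index, and cohort references

Lesion VOIs are accepted as masks drawn upstream (contrast-enhanced T1 or
FLAIR); the contralateral VOI is the left-right mirror across the grid
midline, an involution that conserves voxel count. A lesion crossing the
midline has no contralateral counterpart; the report omits the row with a
warning. Tissue masks come from probability maps thresholded strictly at
0.8, with overlaps resolved to the larger probability (ties to GM) and an
optional ventricle exclusion mask.

The **vascular reactivity index** is the percentage of VOI voxels above the
2-SD threshold, with the *entire* VOI volume as denominator (undefined
voxels count against the index); VOI means, by contrast, are over defined
voxels with counts reported — both literal readings of the definitions.

Cohort aggregation computes per-subject tissue means first and then the
across-subject mean ± SD. The GM/WM ratio is the mean of per-subject ratios,
not the ratio of cohort means: published reference columns (GM/WM ≈ 3.8 with
GM and WM values whose direct quotient is ≈ 3.6) are only consistent with
per-subject averaging, and the two differ on heterogeneous cohorts, which a
test demonstrates. The ratio is not reported for VRM, whose WM means sit
near zero.

## The phantom: what it emulates, what it does not

The generator synthesizes block-design BOLD with per-tissue fractional
amplitudes: signal(t) = baseline · (1 + ΔS/100 · boxcar(t, lag)) ·
(1 + drift · t) + Gaussian noise. The default layout is a slab "brain" with
a GM mantle, WM core, central CSF box and an optional lateralized tumor
sphere, so that a left-right flip lands in healthy tissue. Tumor voxels
split into an *immature* fraction (hyperoxia-responsive, hypercapnia-silent;
optionally with its own elevated O2 amplitude, since angiogenic tissue is
hypervascular) and a mature remainder; a steal region with negative O2
amplitude can be added. Ground-truth maps and masks are returned alongside
every run.

Default study conditions, chosen once to match the healthy-cohort setting
the package targets: 19 subjects; ≈ 7,900 GM and 4,200 WM voxels on a
32 × 32 × 16 grid; tissue amplitudes at the healthy reference means (GM/WM
2.54/0.71% under hyperoxia, 1.33/0.40% under hypercapnia) with
between-subject SDs 0.63/0.30 and 0.33/0.24; voxel noise 0.2% of baseline
(a realistic temporal SNR of 500 for smoothed 3T EPI); drift off by
default. The tumor phantom uses a ≥ 1,000-voxel sphere, immature fraction
0.27, immature O2 amplitude 3.0%, and a mature compartment with a
CO2-dominant balanced response (O2 2.0%, CO2 1.33%) so the two response
classes are separated on either side of the abnormality threshold. The
within-tissue voxelwise amplitude variance is not asserted (no published
value exists); it is config, default 0.

Noise is independent Gaussian per voxel and volume. There is no spatial
autocorrelation, physiological (cardiac/respiratory) noise, T2* physics, or
motion; inputs are assumed motion-corrected and aligned (a center-of-mass
QC check warns when they are not). Passing tests on this phantom therefore
validates estimator correctness and calibration — not robustness to
structured real-world noise.

With these conditions the cohort mean of a tissue amplitude is itself a
19-draw sample mean (SE ≈ 0.14% for GM hyperoxia), which dominates the
recovery error; the mapping step contributes < 0.01%. Simulated cohort
recovery is asserted within ±0.15% absolute accordingly.

## Numerical conventions

* Correlations are clipped to \[−1, 1\]; perfect correlation maps to p = 0;
  constant time series get r = NA, p = 1 and are flagged, not errors.
* Reference SD must be strictly positive; degenerate (constant) reference
  regions are rejected, as are references with fewer than 100 defined
  voxels (configurable).
* Strict `>` at the 0.8 probability and mean + 2 SD thresholds.
* All randomness is seeded; a subject's immature-voxel draw happens once at
  config time so both challenge runs share one ground truth, and runs are
  bit-reproducible for a fixed config.

## Known limitations

Patient-derived quantities (lesion VRM values, patient-table indices)
depend on real acquisitions and are covered only by directional phantom
properties: immature-tumor VRM exceeds mature-tissue VRM, the lesion index
far exceeds the contralateral index, and GM exceeds WM in every simulated
subject. The healthy VRM reference magnitudes produced by the phantom
cohort reflect its independent per-tissue amplitude draws, not the
(unknown) between-subject covariance of real cohorts, so the simulated
across-subject VRM SD should not be read as a physiological estimate.
rCBV maps are consumed, never computed, and registration/segmentation are
upstream concerns.
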