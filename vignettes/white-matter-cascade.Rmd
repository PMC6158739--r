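---
title: "Methods: presymptomatic white-matter diffusion trajectories"
author: "wmcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presymptomatic white-matter diffusion trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In autosomal-dominant Alzheimer's disease every mutation carrier will
develop dementia, and the expected age of onset is inherited, so each
participant can be placed on a common clock: the estimated years from
symptom onset (EYO), negative before the parental onset age. Against that
clock one can ask *when* white-matter microstructure starts to diverge in
carriers, *where* in the white matter it happens first, and how it sits
within the cascade of amyloid, tau, microglial and atrophy biomarkers.

`wmcascade` implements that analysis as a reusable, fully testable pipeline
operating on skeletonized mean-diffusivity (MD) maps (one per subject, all
on a shared white-matter skeleton), a labelled tract atlas, per-subject WMH
masks, a subject table and a biomarker table. Because the motivating cohort
data are access-restricted, the package ships a synthetic cohort generator
that reproduces the *structure* of such a dataset with planted ground truth,
so every stage can be validated end to end.

## Models and procedures

### Voxel-wise inference

At every skeleton voxel we fit the linear model

```
MD ~ 1 + EYO + mutation + EYO:mutation + sex + education
```

and test the `EYO:mutation` interaction — a steeper MD slope against EYO in
carriers than in non-carriers. Significance is assessed non-parametrically:
threshold-free cluster enhancement (TFCE) of the t-map,

```
enhanced(v) = sum over h of extent(v, h)^E * h^H * dh,
```

followed by Freedman–Lane permutation of the reduced-model residuals (the
data are residualized against all nuisance columns, residual rows are
permuted, the full model is refitted) with family-wise-error control by the
permutation distribution of the image-wise maximum enhanced statistic.
Defaults: `H = 2`, `E = 0.5`, 26-neighbour connectivity,
`dh = max(t)/100`, 500 permutations — the standard constants of the TFCE
method and permutation count of the original analysis; none of these is
load-bearing for correctness (the TFCE oracle tests run across
connectivities and step sizes).

### PSMD

The peak-width of skeletonized mean diffusivity is the 95th minus the 5th
percentile of the MD distribution over the (custom) skeleton mask — a single
global number per subject that grows when damage makes the skeleton
histogram more dispersed. Percentiles use linear interpolation between
closest ranks (`quantile` type 7). The "histogram" language of the PSMD
literature is treated as the empirical distribution; no binning is applied,
because binning would coarsen the percentiles for no benefit. Non-finite
voxels inside the mask raise an error rather than being dropped silently —
silent dropping hides upstream masking failures.

### Tract ordering on the EYO grid

Tract ROIs are the intersection of each atlas tract with the significant
interaction mask; tracts whose significant fraction falls below 2% are
excluded (the motivating analysis excluded tracts in a 0.8–1.6% band), with
an a-priori list (by default the hippocampal cingulum) always retained. Per
tract (and for PSMD) the pipeline:

1. removes outliers within carriers and non-carriers separately by the Tukey
   rule `value > median + 1.5 * IQR` — upper tail only, because the
   pathological direction for MD is an increase (configurable to
   two-sided);
2. fits the same five-predictor model by Huber M-estimation (IRLS, MAD
   scale, tuning constant 1.345 for 95% Gaussian efficiency — the default of
   the standard implementation);
3. evaluates the carrier-minus-non-carrier difference on the EYO grid
   −25, −20, …, +10. Covariates cancel in the difference, which is affine in
   the grid value e: `diff(e) = b_mut + e * b_int`, with delta-method
   variance `var(b_mut) + e^2 var(b_int) + 2 e cov(b_mut, b_int)` and
   normal-quantile 95% CIs. The earliest abnormal grid point is the first
   whose CI excludes zero; results are reported as the half-open interval
   `(previous grid value, earliest]`.

A percentile-bootstrap alternative (`ci_method = "bootstrap"`, default 2000
seeded draws, resampling subjects and re-running the filter and fit per
draw) is available; on clean data it tracks the delta-method intervals and
runs somewhat wider where the Tukey filter is active.

**Direction of the abnormality rule.** The published criterion is a 95% CI
excluding zero. We default to the one-sided reading — CI entirely *above*
zero — for a structural reason: a straight line fitted to a ramp-shaped
truth is negative before it crosses zero, so at high signal-to-noise a
sign-agnostic rule certifies a spurious *decrease* at the far pre-onset end
of the grid. Since the phenomenon of interest is an MD increase, the
directional rule is scientifically the right default; `direction =
"two.sided"` restores the literal reading.

### Biomarker trajectories and the cascade

Biomarker-versus-EYO curves are fitted by forward polynomial addition:
starting from the linear model (group, EYO, group × EYO), the next order is
added jointly for the base and interaction polynomial, and fitting stops as
soon as the AIC fails to decrease. Fits use the same robust M-estimation;
the AIC is computed from the Gaussian quasi-likelihood of the robust fit
(a plain least-squares engine is available via `engine = "ols"`). Because
each step adds two parameters, the chance of accepting one spurious extra
order under the null is approximately `P(chisq_2 > 4) ≈ 13.5%`; forward-AIC
selection is therefore expected to pick the generating order about 86–87% of
the time, which the acceptance script measures directly. Hippocampal volume
is pre-adjusted for intracranial volume by the regression approach, with the
slope estimated in non-carriers only so that disease effects cannot leak
into the head-size correction. For the cascade figure all curves are
z-scored against the non-carrier reference and sign-flipped so "abnormal" is
upward; the reference is the mean fitted non-carrier value over the cohort's
EYOs and the SD of observed non-carrier values.

### Projection zones

The terminal direction of a streamline is the normalized mean of
finite-difference tangents at regularly spaced points in its terminal
section (default: last 5 points, spacing 1). From the terminal point the
fibre is marched along that direction in 0.5-voxel steps up to 10 voxels;
voxels traversed inside the grey-matter mask, dilated by 1 voxel (Chebyshev)
and re-intersected with the mask, form the streamline's projection-zone
contribution, and per-tract zones are the union over streamlines and both
ends. The counts and radii are deliberate defaults — the motivating text
specifies "regularly spaced tangents" and "surrounding voxels" without
numbers — and all are arguments. Grey-matter volume in a zone is the sum of
the density image over zone voxels times the voxel volume; tract-MD to
GM-volume associations are robust regressions with sex and education
covariates, Benjamini–Hochberg corrected across tracts.

### WMH analyses

Group frequency maps are voxel-wise means of the binary lesion masks. The
sensitivity analysis recomputes each tract's average MD separately within
WMH voxels and within the normal-appearing remainder (a side with fewer than
5 voxels is reported missing, not zero) and refits the interaction model per
side; subjects without a mask are treated as lesion-free.

## The synthetic cohort: what it emulates, and what it does not

Defaults mirror the motivating study's structure: 64 carriers, 45
non-carriers, EYO uniform on [−25, 10] (the study reports only means ± SDs
of ≈ ±11, which a wide uniform matches; the within-group EYO distribution is
our modelling choice), sex ≈ 1:1, education ≈ 14.5 ± 2.8 years, carriers
symptomatic once EYO > 0. The white-matter skeleton covers ~15% of a
32 × 32 × 16 grid (2.5 mm isotropic affine) and is partitioned into 11
labelled tracts. Per-voxel MD is

```
baseline(v) + carrier * slope(v) * max(0, EYO - onset_t) + covariates + noise
```

with baseline 7.5e-4 mm^2/s plus a fine-scale spatial field (SD 5e-5) that
gives the skeleton histogram a realistic width; a sigmoid effect shape is
available. Tract onsets follow the published ordering (forceps major and
minor at −10, long association fibres at −5, hippocampal cingulum at 0, two
null tracts), with slopes of order 1.5e-6 mm^2/s per year — the scale of the
published global interaction coefficient. Within a tract, voxel slopes are
modulated by `max(0, 1 + z(v))` with a fine-scale field `z`
(`effect_heterogeneity`, default 1): damage concentrates in cluster cores,
which is what makes the skeleton histogram *widen* (the property PSMD
measures) rather than translate. Setting `effect_heterogeneity = 0` gives
exactly uniform tract effects with a closed-form group difference, which the
tests exploit.

Noise is iid Gaussian per voxel, default SD 3e-5 mm^2/s (~4% of baseline),
chosen so the default cohort reproduces the qualitative voxel-wise picture
of the motivating study: peak interaction t ≈ 4.5–5, graded detection across
affected tracts, and exclusion of low-fraction tracts. An optional flag
smooths the noise field to stress TFCE with spatially correlated noise.

Two consequences of iid noise deserve emphasis. First, tract-average MD has
noise ~ `noise_sd / sqrt(tract voxels)`, far cleaner than real tract
averages (real between-subject variation is spatially correlated and does
not average away). Passing tests on this generator therefore demonstrates
*procedural correctness*, not expected field performance. Second, the
earliest-abnormality simulations control the tract-level
noise-to-slope ratio directly; we fix it by a closed-form design analysis
(below) rather than inheriting the optimistic default.

WMH masks are Bernoulli draws per skeleton voxel with probability rising
toward posterior (high y) and periventricular (mid-slice z) coordinates and,
in carriers, with EYO; the probability map is exposed
(`wmh_probability_map`) so law-of-large-numbers checks are exact.
Biomarkers follow monotone ramp trajectories in carriers with onsets in the
published cascade order (PIB-PET and total tau at −20, P-tau at −18,
CSF Aβ42 at −15 falling, sTREM2 at −10, hippocampal volume at −5 falling)
on realistic assay scales. Grey-matter images for the projection stage plant
a configurable negative coupling between a subject's tract MD and density in
that tract's zone. Not emulated: MR physics, registration error,
scanner/site effects, longitudinal visits, family structure.

## Design analysis for the earliest-abnormality simulation

The ordering model is linear in EYO while the planted truth is a ramp, so
the fitted difference line is positive already one grid step before the true
onset (its value at −15 for an onset at −10 is ≈ 1.16 × slope under uniform
EYO on [−25, 10]). A closed-form simulation of the estimator (Tukey filter +
Huber fit + delta CIs, 400 replicates per noise level, run before the
pipeline tests were written) shows the probability of flagging first at
exactly {−10, −5} peaks at ~0.85 for tract-level sigma between 6 and 8 times
the slope: below that window the −15 lobe becomes certain, above it
detection is lost. We therefore fix the design point `sigma_tract = 7 *
slope` for the recovery simulations (`noise_sd = 1.8e-4` on a 307-voxel
skeleton with slope 1.5e-6). Recovery *within one grid step* of the truth is
≥ 0.98 at that point; exact-set recovery cannot exceed ~0.87 under these
conditions for any noise level, a property of the linear-model-on-ramp
design, not of the implementation. The acceptance script reports both rates.

## Numerical choices

- Percentiles and IQR: `quantile` type 7 everywhere (linear interpolation
  between closest ranks), stated because PSMD and the Tukey fence shift by
  O(1/n) across conventions.
- Permutation p-values use the "+1" convention — the observed statistic
  counts as one permutation — so `p >= 1/n_perm` and `n_perm = 1` gives
  p = 1 identically.
- Voxels with zero residual variance get t = 0 with a warning and are
  excluded from the permutation maximum; they carry no evidence and would
  otherwise propagate NaNs.
- TFCE handles signed maps by enhancing the positive and negated parts
  separately; the one-sided maximum is the default test statistic, matching
  the directional hypothesis.
- Continuous voxel coordinates (0-based, centres at integers) are voxelized
  half-up (`floor(x + 0.5)`), not banker's rounding, so integer translations
  commute with voxelization exactly.
- Robust-fit convergence failures warn rather than stop; constant responses
  short-circuit to the exact zero-slope solution.
- Stage seeds are derived deterministically from the single pipeline seed,
  so one config + seed pair fixes the entire manifest byte-for-byte.

## Known limitations

- The generator's iid noise makes tract-level inference optimistic (see
  above); spatially correlated noise is available only as a smoothing flag.
- Earliest-abnormality timing inherits the linear-interpolation bias of the
  published procedure near ramp onsets: expect occasional one-grid-step
  early calls at high SNR.
- Permutations are unrestricted; exchangeability blocks for family
  structure are out of scope.
- The relaxed thin-tract criterion (voxel-wise uncorrected p < 0.01) is
  implemented as an alternative thresholding mode on the t-map
  (`significance_mask(mode = "uncorrected")`); whether the original analysis
  thresholded t- or p-maps voxel-wise is not specified in the source text.
- FA/RD/AD variants are not computed; the pipeline is MD-only, with
  `intersect_binarized_maps` provided for combining externally computed
  index maps.
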