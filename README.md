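# wmcascade

Presymptomatic white-matter diffusion trajectories in autosomal-dominant
Alzheimer's disease, as a tested, reusable R pipeline.

In autosomal-dominant Alzheimer's disease, every mutation carrier is destined
to develop dementia at roughly the inherited parental age of onset, so each
subject can be indexed by **EYO** — estimated years from symptom onset
(negative = presymptomatic). `wmcascade` answers, on skeletonized
mean-diffusivity (MD) data: *when* does white-matter microstructure diverge
in carriers, *where* does it diverge first, and how does it sit within the
amyloid → tau → microglia → atrophy biomarker cascade?

The package implements:

- **Voxel-wise inference**: per-voxel GLM
  `MD ~ EYO * mutation + sex + education`, threshold-free cluster enhancement
  (TFCE: `sum_h extent(v,h)^E · h^H · dh`, H = 2, E = 0.5, 26-connectivity)
  and Freedman–Lane permutation FWE control via the max-statistic null
  (default 500 permutations).
- **PSMD**: the peak-width of skeletonized mean diffusivity,
  `P95 − P5` of the skeleton MD distribution within a custom mask — a global
  marker of heterogeneous white-matter damage.
- **Tract ordering**: atlas ∩ significant-voxel ROIs (tracts under 2%
  significant voxels excluded, a-priori tracts retained), per-group Tukey
  outlier removal (`> median + 1.5·IQR`), Huber M-estimation regression, and
  the carrier-minus-non-carrier difference `diff(e) = β_mut + e·β_int` with
  delta-method 95% CIs on the EYO grid −25…+10 (5-year steps); the earliest
  grid point whose CI excludes zero dates each tract's first abnormality.
  A seeded subject-resampling bootstrap is available behind a flag.
- **Biomarker trajectories**: forward polynomial addition with AIC stopping
  (robust fits), ICV adjustment of hippocampal volume, standardized cascade
  curves, and robust PSMD–biomarker association regressions.
- **Projection zones**: tangent-based extrapolation of streamline terminals
  into grey matter, zone volume extraction, and tract-MD → GM-volume
  robust regressions with Benjamini–Hochberg FDR.
- **WMH analyses**: voxel-wise lesion frequency maps per group, and the
  inside-vs-outside-WMH sensitivity re-fit of the interaction.
- **Synthetic cohort generator**: a familial-AD-style two-group dataset (64 carriers /
  45 non-carriers by default) with planted per-tract MD ramp onsets,
  biomarker trajectories, posterior/periventricular WMH and ground-truth
  output, so every stage is validated against known truth.

## Worked example

```r
library(wmcascade)

res <- run_pipeline(run_config(seed = 1))   # default synthetic cohort
m   <- res$manifest$stages

m$voxelwise$n_significant_voxels
#> [1] 211
round(m$voxelwise$max_t, 2)
#> [1] 5.18
m$ordering$summary[, c("measure", "beta_interaction", "earliest_abnormal")]
#>                 measure beta_interaction earliest_abnormal
#> 1         forceps_major     1.840400e-06               -10
#> 2         forceps_minor     2.076254e-06               -10
#> 3             ifof_left     1.265460e-06                -5
#> 4            ifof_right     1.538789e-06               -10
#> 5              ilf_left     1.595274e-06                -5
#> 6             ilf_right     1.631071e-06                -5
#> 7              slf_left     1.496445e-06                -5
#> 8              atr_left     1.516426e-06                -5
#> 9  cingulum_hippocampus     1.469923e-06                 0
#> 10                 psmd     2.143644e-07               -10
```

Reading this: 211 skeleton voxels show a family-wise-significant
EYO × mutation interaction (peak t = 5.18). At the tract level the callosal
forceps diverge first — their group difference becomes significant at
EYO = −10, i.e. a decade before expected symptom onset, with interaction
slopes of ~1.8–2.1 × 10⁻⁶ mm²/s per year — followed by the long association
fibres at −5 and the hippocampal cingulum only at onset; the global PSMD
marker turns abnormal alongside the forceps. That is the planted cascade:
the generator's true onsets are −10 (forceps), −5 (association fibres) and 0
(cingulum).

Within carriers, PSMD tracks the planted biomarker cascade
(`m$trajectories$psmd_associations`): standardized B = −0.76 for CSF
Aβ₁₋₄₂, +0.71 for total tau, +0.54 for sTREM2, +0.74 for PIB-PET. Higher
tract MD predicts lower grey-matter volume in every tract's projection zone
(`m$projection$associations`: mean B ≈ −0.52, all FDR p < 0.05), and the
interaction survives restriction to normal-appearing (outside-WMH) tissue
(`m$wmh$interaction_comparison`).

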