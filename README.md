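# ironmap

Voxel-wise permutation testing and region-level statistics for thalamic
iron accumulation in phase-filtered susceptibility-weighted MRI (SWI).

## The problem

In several lysosomal storage disorders — aspartylglucosaminuria (AGU) being
the motivating case — iron accumulates inside the thalamus as the disease
progresses. On phase-filtered SWI (with the scanner's "left-handed" phase
convention) more iron means a *brighter* signal, so patient/control cohorts
registered to a common template can be compared voxel by voxel. `ironmap`
is for imaging scientists who want to (i) segment the sub-thalamic regions
where patients' intensities are elevated, without assuming an anatomical
atlas of where iron should accumulate, and (ii) quantify the degree and
age-dependence of that accumulation in a form usable as a treatment-response
biomarker.

## What it computes

**Localizer.** Inside a binary thalamus mask, per-subject intensities are
residualized on age and sex, and each voxel gets the statistic

    T(v) = | mean_patients y(v) - mean_controls y(v) |

which is enhanced by threshold-free cluster enhancement,

    TFCE(v) = ∫₀^hmax  extent(v, h)^E · h^H  dh        (E = 0.5, H = 2),

where `extent(v, h)` is the size of the connected supra-threshold component
containing `v` (26-connectivity by default). The null distribution comes
from random group relabelings (group sizes preserved; exhaustive
enumeration for tiny cohorts), with family-wise error control by Bonferroni
(as in the source method) or by the permutation distribution of the maximum
enhanced statistic (operational default). The extracted region is the set
of FWE-significant voxels with a positive patient-minus-control difference.

**Region statistics.** On per-subject average intensities over the whole
mask and over the extracted region: group summaries; Cohen's D for unequal
variances `|m₁ − m₂| / √((v₁ + v₂)/2)`; Welch's t-test; the additive
two-way ANOVA age effect; an effect-coded regression
`y = b + Δb·g + a·x + Δa·g·x` (patients `g = +1`, controls `g = −1`) with
per-group R²; and a sequential ANCOVA whose Group×Age interaction measures
the group difference in the iron-accumulation rate.

**Synthetic cohorts.** A calibrated generator plants spherical
iron-accumulation clusters in a two-ellipsoid "thalamus" and draws
intensities whose region-level means, variances and age slopes reproduce
the published AGU cohort structure (16+16 subjects, in-region means ≈
−258/402, patient slope ≈ 53 intensity units/year), so the entire pipeline
is testable without clinical data. Minimal NIfTI-1 I/O is built in.

## Worked example

```r
library(ironmap)

cohort <- generate_cohort(simulation_config(rng_seed = 11))
stack  <- cohort_to_stack(cohort)
pmaps  <- localize_regions(stack, cfg = perm_config(1000, rng_seed = 12))
print(pmaps)
dice(pmaps$region, truth_region_vector(cohort, stack))
report <- stats_report_from_stack(stack, pmaps$region, mask_name = "iron_region")
print(report)
```

prints (abridged):

```
<voxel_pmaps> 1304 voxels, 1000 permutations, FWE: max_statistic (alpha 0.05)
  significant region: 233 voxels; min adjusted p = 0.000999
[1] 1                                   # Dice overlap with the planted truth
== Region statistics report (iron_region, n = 32) ==
Step 1: group summaries
  control  n = 16  mean =  -242.63  variance =    1889.74
  patient  n = 16  mean =   210.60  variance =   28668.48
Step 2: Cohen's D (unequal variances) = 3.67
Step 3: Welch t-test (two.sided): t = 10.37, df = 17.0, p = 9.22e-09
Step 5: ...
  Slope a          23.80      5.05    4.71   0.000
  da Patients      31.71      5.05    6.28   0.000
  R^2: controls 0.37, patients 0.65
Step 6: ...
  Group x Age    1      236705.62      236705.62    39.42   0.000
  Error         28      168147.16        6005.26
```

The localizer recovers the planted clusters exactly (Dice 1.0). The
region report then reads like the clinical analysis it emulates: a very
large group difference (Cohen's D ≈ 3.7), a grand age slope `a ≈ 23.8`
intensity units/year with a strongly positive patient deviation `Δa`
(planted values 23.73 and 29.46), a patient-only age correlation
(R² 0.65 vs 0.37), and a highly significant Group×Age interaction on
28 error degrees of freedom — i.e., iron accumulates with age in patients
but not controls.

A command-line front end with `simulate` / `localize` / `stats` / `run`
verbs lives in `inst/cli/ironmap.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates, from scratch, the pipeline's empirical family-wise type-I
error rate: 200 independent null cohorts (16+16 subjects, 96-voxel mask,
iid Gaussian intensities, no group effect) are each run through the full
localizer (2,000 permutations, TFCE, Bonferroni at alpha 0.05), and the
fraction of cohorts with any significant voxel is written as JSON.
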