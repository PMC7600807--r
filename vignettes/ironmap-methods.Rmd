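---
title: "Methods: permutation localization and region statistics for thalamic iron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation localization and region statistics for thalamic iron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`ironmap` analyses cohorts of pre-registered 3D volumes (phase-filtered
SWI, or any modality where a group's intensities are hypothesized to be
elevated) under a binary mask. It makes no attempt at registration,
atlas lookup, bias correction or phase unwrapping: volumes are assumed to
share the mask's grid and affine (checked to an absolute tolerance of
1e-4), and intensities are treated as unitless reals on whatever scale the
reconstruction produced. Statistically it consists of two layers:

1. a **voxel-wise permutation localizer** that segments the mask into the
   sub-region where the patient group's covariate-adjusted mean intensity
   is elevated, and
2. a **region-level six-step suite** on per-subject average intensities:
   group summaries, Cohen's D for unequal variances, Welch's t-test, the
   additive two-way ANOVA age effect, an effect-coded multivariate
   regression, and a sequential ANCOVA with a Group×Age interaction.

### The localizer

Let `Y` be the subjects × in-mask-voxels matrix. Each column is replaced
by its residuals from an OLS fit on `[1, age, sex]`. Group labels are not
in that nuisance model; the permutation then shuffles labels over the
residualized rows (the common "residualize once, permute labels" scheme).
The alternative — re-estimating the nuisance fit inside every permutation,
as in Freedman–Lane — is statistically defensible too; we chose the simpler
scheme because it is deterministic, fast, and its behaviour under the null
is verified directly by simulation in the test suite. The scheme is
recorded in each run's metadata.

The voxel statistic is the **absolute** difference of group means of the
adjusted intensities. The working hypothesis is one-sided (iron raises
phase-filtered intensity), and both sentences are honoured: the absolute
statistic is used exactly as defined, and one-sidedness is enforced at
region-extraction time by intersecting the significant set with
`patient mean − control mean > 0` (`direction_constraint`, default on).

TFCE enhances each voxel to the Riemann sum

\[ \mathrm{TFCE}(v) \;=\; \sum_{i=1}^{n} e(v, h_i)^{E}\, h_i^{H}\, \Delta h,
   \qquad h_i = i\,\Delta h,\; \Delta h = h_{\max}/n , \]

with `E = 0.5`, `H = 2`, `n = 100` steps and 26-connectivity by default —
the enhancement method's standard values, since the source analysis states
none. The right-endpoint sum overestimates the ideal integral by a factor
`(1 + 1/n)(1 + 1/2n)` (about 1.5% at `n = 100`), which is why the test
suite's closed-form checks carry a 2% tolerance. Two numerical details
matter: the top threshold is computed as `hmax * n/n` rather than
`n * (hmax/n)` so that floating-point overshoot cannot silently drop the
maximum voxel's top step, and components are maintained incrementally with
a union–find as thresholds descend, making one enhancement
O(steps × voxels) after a sort.

The permutation null relabels subjects with group sizes preserved, drawing
labelings with replacement from the labeling space. When the number of
distinct labelings `C(n, n_patients)` is below the requested count the
test switches to exhaustive enumeration (with a notice); p-values are then
exact rational counts `#{T ≥ T_obs}/N`. In Monte-Carlo mode the observed
labeling counts as one extra permutation, `p = (1 + c)/(1 + N)`, so `p > 0`
and the test is valid; ties count toward the tail (conservative).

**FWE control.** Bonferroni (`p_voxel × n_voxels`, capped at 1) is
implemented as the source analysis states, but it interacts badly with
permutation granularity: with `N` permutations the smallest attainable
per-voxel p is ≈ `1/N`, so Bonferroni over more than about `α·N` voxels can
never reject — the package warns when this floor applies. The operational
default is therefore max-statistic FWE, which compares each observed
enhanced value against the permutation distribution of the map-wise
maximum and adapts to the spatial dependence TFCE induces. Whether the
published analysis thresholded per voxel or per cluster is not stated; we
threshold per voxel.

### The region suite

Effect coding is sum-to-zero with patients `g = +1`: the published
coefficient tables print mirror-image ± deviations sharing one standard
error, which forces exactly this coding. ANCOVA uses sequential (Type I)
sums of squares in the fixed order Group, Age, Group×Age — matching the
printed row order and making the decomposition identity
`SS_Group + SS_Age + SS_GxA + SS_Error = SS_total` exact; the error row has
`n − 4` degrees of freedom. The "two-way ANOVA" age step is implemented as
the sequential additive model `y ~ Group + Age`, the interaction-free
sibling of the ANCOVA. Sample variances use denominator `n − 1`; the Welch
test defaults to two-sided (the published whole-thalamus p of 0.01 is the
two-sided value of the printed summaries, ≈ 0.013). Standard fits go
through `stats::lm`/`anova`; the package's own contributions (the
permutation/TFCE machinery, Cohen's D for unequal variances) are
implemented here and cross-checked in the tests against independent
brute-force oracles.

## The synthetic cohort generator

The generator emulates the published cohort as a *stated world*, not a
tunable benchmark. Subject `i`, voxel `v`:

\[ y_{iv} = \mu_0 + \varepsilon_{iv}, \qquad
   \varepsilon_{iv} \sim N(0, \sigma_0^2), \]

plus, for voxels in the planted truth region,

\[ \text{patients: } +\; \beta_0 + \beta_a\,\mathrm{age}_i + u_i, \qquad
   \text{controls: } +\; \gamma_a\,\mathrm{age}_i + u_i , \]

with `u_i ~ N(0, τ_group²)` a **per-subject** iron-load deviation shared
across the subject's region voxels. Making `u_i` subject-level rather than
voxel-level is deliberate: the published calibration targets are variances
of *region means*, and purely voxel-wise noise would be averaged away by
the region mean, leaving the group variances unreproducible.

Defaults and their provenance:

| parameter | default | rationale |
|---|---|---|
| `n_per_group` | 16 | published cohort size |
| ages | uniform on 3.4–17.0 (patients), 7.1–16.7 (controls) years | only ranges and moments are printed; uniform is the least-assumptive fit of a range, and the implied means (10.2, 11.9) approximately honour the printed 10.3 ± 4.0 and 11.6 ± 3.2 |
| `baseline_mean` `μ0` | −191.79 | control in-region intercept, `b + Δb_controls = −169.77 − 22.02` |
| `cluster_intercept` `β0` | +44.04 | patient-minus-control intercept gap, `2 × 22.02` |
| `cluster_age_slope` `βa` | 53.19 /year | grand slope + patient deviation, `23.73 + 29.46` |
| `control_age_slope` `γa` | −5.73 /year | `23.73 − 29.46` |
| `cluster_noise_sd` `τ` | (41.23, 159.58) | solved so in-region group variances reproduce 1952 and ≈ 68,216 given the uniform age spreads, under the constraint that the pooled residual mean square equals the printed 13,582.28: `τ_c² = 1952 − γa²·Var(age_c)`, `τ_p² = 2·13582.28 − τ_c²` |
| `baseline_sd` `σ0` | 50 | per-voxel noise; no voxel-level dispersion is published, so this is a fixed realism choice on the same scale as the control region noise — large enough that single voxels are uninformative, small enough that a 16+16 cohort separates a true cluster |
| grid / mask | 32³, two ellipsoids ≈ 1,300 voxels | desk-scale permutation testing with nontrivial 3D cluster geometry |
| clusters | 3 spheres, radius 2.5 voxels | accumulation concentrates in a few compact sub-structures; shapes are unreported, spheres are the neutral choice |
| sexes | `round(n × sex_ratio)` females, order shuffled | reproduces the published 8F/8M patients exactly; the control group's 10F/6M cannot be expressed by one shared ratio and is approximated at 8F/8M |

Intensities are unitless on the printed scale (values like −258 … 402);
phase-filtered SWI has no published physical unit. The generator does
**not** simulate k-space, phase wrapping, the scanner's filtered-phase
reconstruction, registration error, anatomy, or spatial noise correlation.
A green end-to-end test therefore establishes that the *statistical*
machinery behaves as designed under the published effect structure — not
that the pipeline is robust to registration artifacts or structured
physiological noise.

## Design decisions worth knowing

* **Coverage is checked under homoskedastic noise.** The slope-deviation
  recovery experiment uses a single residual sd `√13582.28` for both
  groups, which is the model under which the OLS 95% interval for `Δa` has
  exactly nominal coverage. With the generator's heteroskedastic per-group
  default the OLS interval is *conservative* (roughly 98% empirical
  coverage): the control age range spans about half the patients' range,
  so the pooled error variance over-weights the noisy patient slope — an
  instructive mismatch, but not the stated recovery model.
* **Null FWE is measured on the pipeline's extracted region**, i.e. with
  the direction constraint on, because that is the decision the pipeline
  actually emits; the undirected `p_adjusted < α` rate is bounded by the
  Bonferroni union bound `n_voxels/(N+1)` regardless.
* **Exact-test permutation count.** The source text cites ≈ 6.3 × 10²¹
  permutations for an exact 16+16 test; the number of distinct two-group
  relabelings is `C(32,16) ≈ 6.0 × 10⁸`. The implementation counts
  distinct labelings and does not reproduce the larger figure (which
  matches no standard counting of this design).
* **A worked-example inconsistency.** For Cohen's D with unequal
  variances the definition `|m₁−m₂|/√((v₁+v₂)/2)` reproduces the published
  iron-region value 3.52 from the printed summaries exactly, and is the
  formula implemented; the published whole-thalamus D (0.97) back-computes
  to ≈ 0.94 from the *rounded* printed summaries, presumably because
  unrounded means were used there.
* **Degenerate inputs.** All-zero statistic maps enhance to zero (not an
  error); empty masks, empty regions, single-group cohorts and
  both-variances-zero effect sizes raise explicit errors; rank-deficient
  nuisance designs fall back to the maximal full-rank column subset with a
  warning; cluster placement failure after bounded retries is an explicit
  error rather than a silent smaller region.
* **Determinism.** Every stochastic step is seeded; a pipeline run derives
  its stage seeds from one global seed, records them in `run_metadata.txt`,
  and reproduces its TSV and NIfTI outputs byte for byte. Voxel ordering
  inside a mask is fixed to lexicographic (column-major) scan order.

## Limitations

Real SWI data carry spatially correlated noise, subject-specific
anatomy and registration error that the simulator does not model, so the
Dice-recovery and FWE results here are best-case calibrations of the
statistics, not of an imaging pipeline. The published real-data
coefficients (whole-thalamus D = 0.97, patient R² = 0.65 in the iron
region) are not reproducible without per-subject data, which were never
deposited; they enter only as calibration targets for the generator and as
oracle arithmetic on printed summaries.
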