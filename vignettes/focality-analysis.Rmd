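---
title: "Modeling tDCS focality and its anatomical correlates with focalflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tDCS focality and its anatomical correlates with focalflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalflow)
```

## The scientific question

Transcranial direct current stimulation injects a weak direct current
(1–2 mA) through two scalp electrodes. Whether the target region
actually receives a focused dose varies strongly between people even
when the montage is identical, and the leading anatomical explanation is
the distribution of cerebrospinal fluid: CSF conducts at 1.65 S/m,
roughly six times better than gray matter (0.276 S/m) and thirteen times
better than white matter (0.126 S/m), so regional CSF pockets act as
channels that steer the current on its way from anode to cathode.

`focalflow` operationalizes this question as a testable pipeline:

1. simulate the current-density field for a montage on a multi-tissue
   head model;
2. summarize focality per subject with the dose-target-determination
   index (DTDI) and classify subjects as focal (DTDI ≥ 0.75) or
   non-focal;
3. measure regional CSF/GM/WM volumes with partial-volume accounting;
4. scan all regions with three-way (age group × sex × focality) ANOVAs
   to find "focal ROIs" whose tissue volume separates the two groups,
   then characterize them with post-hoc contrasts, correlations against
   the delivered current density, and a DTDI-threshold sweep.

Everything runs on synthetic phantoms and seeded cohort generators, so
the full chain is reproducible and testable on a laptop with no imaging
data.

## The head phantom

A phantom (`phantom_spec()`, `make_phantom()`) is a voxel grid of five
concentric shells — WM core, GM, CSF, skull, skin — centered in the
grid. Default geometry: 48³ voxels at 1.25 mm, shell radii 12 / 18 /
20.5 / 23.5 / 26.5 mm. These radii keep the proportions of a scaled-down
head (a thin, highly conductive CSF layer beneath a resistive skull)
while keeping the linear systems desk-sized.

Two choices matter downstream:

* **Partial volume is real, not cosmetic.** At every shell boundary a
  linear ramp exactly one voxel wide splits the voxel between adjacent
  tissues, and an explicit background (air) component makes the six
  fractions sum to exactly 1 in every voxel. This is the simplest
  construction that makes fractional volumetrics non-trivial and gives
  the volumetrics module honest mixed voxels to integrate.
* **The parcellation is angular.** The brain compartment is divided
  into `n_rois` (default 12) angular sectors about the z axis, with
  sector 1 centered under the default anode. A sector parcellation is
  deliberately coarse compared with an anatomical atlas of 116 regions,
  but it preserves the one geometric property the mechanism depends on:
  there are ROIs directly under each electrode and ROIs lying between
  them on the current path.

Electrodes are spherical caps on the scalp (default geodesic radius
8 mm, i.e. an area of ~2 cm², which is a 25 cm² pad scaled by the square
of the phantom-to-head radius ratio). Montage geometry is expressed as
the angle between the caps: 180° apart emulates an inter-hemispheric
montage, 60° an intra-hemispheric one. Real 10–20 electrode coordinates
are intentionally out of scope.

`inject_csf_pocket()` is the synthetic lever for the mechanism under
study: it converts GM/WM fraction to CSF inside one ROI, filling voxels
nearest the CSF shell first, until a requested volume (ml) has been
added — per-voxel closure is preserved exactly and the last voxel is
converted partially so the added volume is met exactly.

## The solver

The quasi-static volume-conductor equation ∇·(σ∇V) = 0 is discretized on
the voxel grid with a 7-point stencil. Numerical choices:

* **Harmonic-mean face conductances.** The conductance of the face
  between voxels with conductivities σᵢ, σⱼ is 2σᵢσⱼ/(σᵢ+σⱼ)·h. This is
  the standard flux-conserving stencil for discontinuous coefficients;
  with it, the discrete solution of a layered slab is exact, which is
  what the closed-form tests exploit.
* **Dirichlet electrodes plus post-hoc rescaling.** V = 1 on anode
  voxels, V = 0 on cathode voxels, natural (zero-flux) conditions
  elsewhere; the solution is then multiplied by the constant that makes
  the total anode current equal the dose. By linearity this is exact and
  avoids modeling contact impedance. It also makes dose scaling free:
  a 2 mA field is exactly twice the 1 mA field, so DTDI is exactly
  dose-invariant here. (On real heads a dose non-linearity has been
  observed empirically; a linear quasi-static solver cannot and should
  not reproduce it, which is a stated fidelity limit of this model.)
* **Direct sparse factorization.** The reduced system is symmetric
  positive definite and desk-scale (≲ 2·10⁵ unknowns), so it is solved
  by sparse Cholesky (`Matrix`), and the relative residual — typically
  ~10⁻¹⁴, always checked against the 10⁻⁸ contract — is reported in the
  diagnostics. An iterative Krylov solver would add tuning surface
  without benefit at these sizes.
* **Insulator floor.** Voxels below 10⁻⁶ S/m (air, 2.5·10⁻¹⁴ S/m) are
  excluded from the system as perfect insulators; they receive V = 0 and
  J = 0. Including air would raise the condition number by ~14 orders of
  magnitude for no physical gain.
* **Flux-consistent J.** The per-voxel current density averages the
  current densities of the voxel's faces (one-sided at domain
  boundaries). In homogeneous regions this reduces to the
  central-difference gradient; across conductivity interfaces it keeps
  the normal component of J continuous, which a naive central difference
  violates badly (it smears the field kink over two voxels).

`check_conservation()` closes the loop: anode influx, cathode outflux
and the net flux through an interior control box are recomputed from the
face currents, with a 0.1% pass gate relative to the injected current.

Conductivities default to the standard literature set used by
current-flow simulators (WM 0.126, GM 0.276, CSF 1.65, skull 0.01, skin
0.465, air 2.5·10⁻¹⁴, gel 0.3, electrode 5.9·10⁷ S/m); the hard
segmentation feeding the solver picks each voxel's max-fraction tissue
with ties broken toward the more conductive tissue
(CSF > GM > WM > skull > skin > air).

## DTDI and classification

`dtdi()` divides the target ROI's mean |J| by the maximum ROI-level mean
|J|. The denominator includes the target, so the index is guaranteed to
lie in [0, 1] and equals 1 exactly when the peak forms at the target.
(An alternative reading — peak over *intermediary* regions only — would
allow values above 1; the bounded form is the one consistent with the
index's stated range and is the one implemented.) Classification at
0.75 is boundary-inclusive: DTDI = 0.75 is focal. ROI means use the
magnitude of J, not the vector mean, matching how delivered dose is
summarized in this literature.

`threshold_sweep()` lowers the threshold in 0.01 steps, reclassifies,
re-runs the scan, and stops at the first threshold whose focal-ROI set
differs from the starting one; "consistency" is operationalized as *the
same set of focal ROIs significant at corrected α*, the strictest
reading of findings staying unchanged.

## Volumetrics

Regional tissue volume is the sum of tissue fraction × voxel volume over
the ROI's voxels (1 ml = 1000 mm³), so mixed voxels contribute to
several tissues at once. TIV is CSF + GM + WM only — skull and skin are
excluded by definition — and is computed over all brain voxels, so
summed regional volumes equal TIV exactly under full parcellation
coverage and fall short under partial coverage. No threshold suppresses
the small GM/WM volumes that partial-volume effects leave inside
CSF-dominated regions; none is prescribed, and suppressing them would
bias the CSF story the pipeline exists to test.

Residualization (`residualize_covariates()`) replaces volume columns by
OLS residuals on an intercept, the age-group code (young = 0, middle =
1, older = 2) and a sex indicator. Age enters as the 3-level code
because the cohort model carries groups, not continuous ages. The
operation is idempotent to numerical precision.

## The statistical scan

`three_way_anova()` fits the between-subjects factorial with sum-to-zero
contrasts and reports Type-III sums of squares for all seven effects.
Type III was chosen because focal/non-focal group sizes are inherently
unequal — the classification is data-driven — and Type III is the
decomposition whose hypotheses do not depend on cell counts; on balanced
data it coincides with the sequential decomposition, which is one of the
oracle tests. The implementation computes each effect's SS as the
residual-sum difference between the full model and the model with that
effect's columns removed, batched over all ROI × tissue dependent
variables through shared QR factorizations; this is what makes
2000-replicate null calibrations of the whole scan affordable, and it is
verified against `car::Anova` and `aov` in the tests.

`focal_roi_scan()` flags an ROI when any tissue shows a
corrected-significant focality main effect or interaction containing
focality; age- or sex-only effects never flag. The Bonferroni family is
a configuration knob with three settings:

* `per_tissue` (default): m = number of ROIs, applied within each
  tissue — the conventional ROI-scan correction;
* `rois_by_tissues`: m = ROIs × tissues;
* `scanwide`: m = ROIs × tissues × the four focality-involving effects,
  which controls the family-wise error of the *entire* scan.

These differ in what "family" means, and the package treats that as an
analysis decision rather than hiding one choice: per-tissue correction
controls each tissue-effect family at α but the whole scan's false-flag
probability is necessarily higher (three tissues × four effects are
tested); `scanwide` buys whole-scan control at a real power cost. The
acceptance tests measure both operating points.

Post-hoc contrasts (`posthoc_focality()`) compare focal vs non-focal
estimated marginal means (averaged over sex) within each age group,
using the pooled ANOVA error term and Bonferroni over the three age
groups; they are verified against `emmeans`. Correlation analysis
(`pearson_with_diagnostics()`) reports Pearson r with its t-test,
White's heteroscedasticity test in the Lagrange-multiplier form n·R² of
the auxiliary regression of squared residuals on {x, x²} (χ² with 2 df,
delegated to `lmtest::bptest(..., studentize = TRUE)`), and per-group
correlations compared with the Fisher z statistic
z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3)). All tests are
two-sided by default with one-sided options exposed explicitly — with
group correlations like r = 0.28 (n = 138) vs r = 0.09 (n = 162) the
two-sided Fisher test does not reach 0.05, so sidedness genuinely
matters and is never chosen silently. A Shapiro-Wilk gate and a
Brown-Forsythe (median-centered Levene) homogeneity check accompany the
ANOVA; Mauchly's sphericity test is *not* provided, because sphericity
is undefined for a purely between-subjects design.

## The cohort generators

Table mode (`sample_cohort_tables()`) draws, for the 3 age × 2 sex
design, per-ROI volumes from a Gaussian additive model: volume =
baseline + noise_sd · (age_csf_slope · age + interaction_delta ·
1[focal ∧ older ∧ ROI = target of the effect] + ε). Gaussian synthesis
is the faithful family here because the downstream ANOVA assumes
normality; effects are expressed in units of the noise SD so that
"a 1-SD interaction" means the same thing at any baseline. Defaults:
noise 0.5 ml; baselines 3 / 40 / 35 ml CSF/GM/WM per ROI, giving a TIV
near 940 ml for 12 ROIs — a plausible scaled head; age slope 0.5 SD per
level, reflecting the robust age-CSF association this literature takes
for granted. The target-ROI current density is built as
ρ·z + √(1−ρ²)·ε from the standardized realized CSF of the effect ROI, so
the requested correlation ρ is realized in expectation, and DTDI values
are drawn from truncated normals consistent with the class labels
(≥ 0.75 iff focal). The truncated parents are moment-matched to the
requested class moments (defaults 0.87 ± 0.11 focal, 0.56 ± 0.18
non-focal); note the focal-group dispersion sits near the theoretical
maximum for any distribution on [0.75, 1], so a unimodal truncated
normal reproduces the mean exactly but compresses that SD — a documented
limit of the family, not a bug.

Phantom mode (`simulate_cohort()`) samples a CSF pocket volume per
subject (base 1 ml + 0.5 ml·(age slope + noise), truncated to the ROI's
convertible capacity), injects it, runs the solver, and records ROI
densities, DTDI, classification and volumetrics. The solve runs once per
subject at 1 mA and is rescaled exactly for other doses. Phantom-mode
cohorts demonstrate the physical mechanism (a pocket between the
electrodes raises the target's current density monotonically — a solver
test); table mode supplies the statistical power studies, because
phantom cohorts large enough for ANOVA would spend minutes of solver
time to test what the Gaussian model states directly.

What the generators do *not* emulate: gyrification and real cortical
geometry, MRI noise and segmentation error, registration/normalization
steps, skull inhomogeneity, or the empirical dose non-linearity. Passing
tests therefore certify the pipeline's correctness and calibration under
its stated model, not fidelity to any individual head.

## Problem sizes and reproducibility

The test suite and the acceptance script use 32³ solver grids
(~3·10⁴ unknowns, sub-second solves), 60³ grids at 1 mm for analytic
shell-volume recovery, 300-subject table-mode cohorts, 1000–2000
replicates for null calibrations and 100–200 replicates for power and
sign-recovery studies — sizes chosen so the entire suite completes in a
couple of minutes while keeping Monte-Carlo standard errors a few times
smaller than the margins being tested. All randomness flows from
explicit seeds; `run_pipeline()` derives one sub-stream per montage
geometry so that 1 mA and 2 mA runs of the same montage share their
subjects, which is what makes pipeline-level dose invariance exact. A
degenerate scan design in a pipeline run (e.g. a tiny cohort whose
subjects all classify the same way) is recorded in the report and the
remaining outputs are retained, rather than discarding the run.

## Known limitations

* Finite differences on voxel grids are a fidelity reduction relative to
  tetrahedral FEM on segmented MRIs; the solver is validated against
  closed forms, not against anatomy.
* The parcellation is a 12-sector stand-in for an anatomical atlas;
  "ROI" granularity is structural, not anatomical.
* Aggregating |J| over voxels stands in for averaging over mesh nodes;
  the equivalence is assumed, not established.
* The linear solver cannot express dose non-linearities; DTDI
  dose-invariance is a property of the model, not a claim about tissue.
* Bonferroni is the only multiplicity correction offered, in three
  family sizes; FDR-style procedures are out of scope.
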