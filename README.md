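# focalflow

Why does the same transcranial direct current stimulation (tDCS) montage
stimulate the target region well in one person and poorly in the next?
A large part of the answer is anatomy: the volumes of cerebrospinal fluid
(CSF), gray matter (GM) and white matter (WM) under each region steer the
injected current, because CSF (1.65 S/m) conducts an order of magnitude
better than cortex (GM 0.276 S/m, WM 0.126 S/m). `focalflow` is an R
toolkit for studying this mechanism end to end on synthetic head
phantoms: it simulates quasi-static current flow, quantifies stimulation
focality per subject, derives partial-volume regional volumetrics, and
runs the region-of-interest (ROI) statistical scan that identifies the
regions whose tissue volume separates focally from non-focally
stimulated subjects. It is aimed at researchers in NIBS (non-invasive
brain stimulation) methods and at statisticians who want a fully seeded,
downloadless testbed for this class of analyses.

## The model in brief

**Current flow.** A head phantom is a voxel grid of concentric tissue
shells (skin, skull, CSF, GM, WM) with one-voxel partial-volume ramps at
every boundary, an angular-sector ROI parcellation of the brain
compartment, and two spherical-cap electrodes on the scalp. The
quasi-static volume-conductor equation ∇·(σ∇V) = 0 is discretized with a
7-point finite-difference stencil using harmonic-mean face conductances,
solved with Dirichlet electrode potentials, and rescaled so the injected
current matches the dose (1 or 2 mA); the current density is
J = −σ∇V in mA/m².

**Focality.** Per subject, the mean |J| of every ROI is computed and the
dose-target-determination index is

```
DTDI = mean |J| at the target ROI / peak ROI-mean |J|        ∈ [0, 1]
```

Subjects with DTDI ≥ 0.75 form the *focal* group, the rest the
*non-focal* group (the threshold is inclusive, and the index is
dose-invariant in a linear conduction model).

**Volumetrics.** Regional CSF/GM/WM volumes are partial-volume sums
(fraction × voxel volume, in ml), scaled by the total intracranial
volume TIV = CSF + GM + WM, optionally residualized on age group and
sex.

**The scan.** For every ROI × tissue volume, a three-way between-subjects
ANOVA (age group × sex × focality; Type-III sums of squares under
sum-to-zero contrasts) is run. An ROI is a **focal ROI** when any tissue
shows a Bonferroni-corrected significant focality main effect or any
interaction involving focality. Post-hoc contrasts on estimated marginal
means decompose the effect by age group; Pearson correlations (with
White's heteroscedasticity test and Fisher-z group comparisons) link the
focal ROI's CSF volume to the current density at the target; an
iterative sweep lowers the DTDI threshold in steps of 0.01 until the
findings change.

Seeded generators produce both phantom-mode cohorts (every subject gets
an injected CSF pocket and a full solver run) and table-mode cohorts
(Gaussian volume model with controllable age × focality interaction and
CSF-density correlation), so every stage is testable without MRI data.

## Worked example

```r
library(focalflow)

# a 32^3 phantom with an intra-hemispheric montage (electrode caps 60 degrees apart)
spec <- phantom_spec(grid_shape = c(32, 32, 32), voxel_size_mm = 2,
                     shell_radii_mm = c(wm = 12, gm = 18, csf = 20.5,
                                        skull = 23.5, skin = 26.5),
                     electrode_centers = list(anode = c(1, 0, 0),
                                              cathode = c(cos(pi/3), sin(pi/3), 0)))
ph <- make_phantom(spec)
field <- tdcs_solve(ph, current_mA = 1)
check_conservation(field)$anode_mA
#> [1] 1                                  # injected current recovered exactly

dens <- roi_mean_density(field, phantom_parcellation(ph))
head(dens, 2)
#>   roi  name n_voxels mean_mA_m2
#> 1   1 roi01      412   409.2368
#> 2   2 roi02      382   510.3169
dtdi(dens, target_roi = 1)
#> [1] 0.8019343                          # >= 0.75, so this subject is "focal"

# table-mode cohort: 300 subjects, a 1.5-SD age x focality CSF effect at ROI 5
ch <- sample_cohort_tables(effect_spec(n_per_cell = 50, seed = 42,
                                       interaction_delta = 1.5,
                                       target_density_corr = 0.16))
focal_roi_scan(ch)
#> focal-ROI scan: 12 ROIs x 3 tissues, Bonferroni m = 12 (per_tissue), alpha = 0.05
#> focal ROIs: roi05
#>     roi tissue             effect        F            p  p_corrected
#> 1 roi05    csf           focality 13.51779 2.818515e-04 3.382218e-03
#> 2 roi05    csf age_group:focality 28.08854 7.176618e-12 8.611941e-11

posthoc_focality(ch, "roi05", "csf")[3, c("age_group", "estimate", "p_corrected")]
#>   age_group  estimate  p_corrected
#> 3     older 0.7845469 4.204369e-14   # the difference lives in the older group

pearson_with_diagnostics(ch$roi05_csf_ml, ch$target_density_mA_m2, by = ch$focality)
#> Pearson r = 0.232 (n = 300, p = 5.15e-05); White test LM = 2.31 (p = 0.314)
#>      group         r   n
#> 1    focal 0.3069006 154
#> 2 nonfocal 0.1508980 146
#> group comparison: z = 1.415, p = 0.157
```

The scan flags exactly the seeded region through the CSF
age × focality interaction, the post-hoc contrast localizes the
difference to the older group (focal group higher), and the focal ROI's
CSF volume correlates positively with the current density delivered to
the target — the full chain from conductivity physics to the statistical
fingerprint.

A command-line front-end for batch runs lives in `inst/cli/focalflow.R`
(`run`, `phantom`, `scan`, `sweep` subcommands over the same functions).

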