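# dmndyn

Task-dependent reorganization of default-mode network (DMN)
connectivity, as a reproducible analysis pipeline over synthetic BOLD
cohorts.

## The problem

Seed-based resting-state fMRI shows the DMN as a set of regions
(posterior cingulate, medial prefrontal, lateral parietal and temporal
cortex) coherently fluctuating at rest.  In a four-stage design —
pre-task rest (R1), a relaxed visual classification task (T1), a
speeded version (T2), post-task rest (R2) — parts of the network
desynchronize from the core during task states ("decreasing" regions),
regions outside the network couple into it ("increasing" regions,
salience-network-like), and a stable core persists throughout.  The
degree of within-network desynchronization tracks reaction time and
the degree of outside-network integration tracks accuracy.

This package implements that analysis end to end and, because no scan
data accompanies the design, a calibrated synthetic-cohort generator
that emulates its statistical structure: 19 subjects × 4 states × 150
volumes at TR = 2 s, state-dependent latent inter-region correlations,
between-subject heterogeneity, motion spikes for censoring, and
behaviour coupled to per-subject connectivity change.

## The method in brief

Per run, with `X_v(t)` the voxel series: drop 10 volumes, smooth (8 mm
FWHM), band-pass 0.008–0.08 Hz, regress WM/CSF/global/6 motion
parameters, and censor frames where both the global-signal change
(≥ 0.5%) and framewise displacement (≥ 0.5 mm) hit threshold (the
frame, one before, two after; > 60 removed volumes excludes the run).
Seed connectivity is `z_v = atanh(cor(X_v, s))` with `s` the mean of an
8 mm sphere at (0, −53, 26).  Group maps use one-sample t-tests with
Benjamini–Yekutieli FDR (q = 0.05).  Within the union of the four state
maps, a one-way repeated-measures ANOVA (`F = MS_state/MS_error`, df 3,
3(n−1)) finds state-dependent voxels; clusters > 5 voxels are
classified by a paired t-test of mean(T1,T2) vs mean(R1,R2) into
decreasing/increasing regions; stable regions appear in all four maps
with no ANOVA change.  System-level mean FC (within and between the
three systems) is compared across consecutive states, and per-subject
`dFC = meanFC(task) − meanFC(R1)` is correlated with RT and accuracy
with 1000-resample percentile bootstrap CIs.  A group spatial ICA arm
(MDL order, infomax, template matching, GICA back-projection) validates
the seed-based regions data-drivenly.

## Worked example

```r
library(dmndyn)

scenario <- make_scenario(n_subjects = 16)   # packaged default calibration
res <- run_seed_pipeline(scenario, seed = 1)

res$region_set
#> <region_set: 7 stable, 4 decreasing, 4 increasing>

comp <- res$summaries$subject %in% sprintf("sub%02d", res$complete)
round(group_mean_fc(res$summaries[comp, ])[1:2, ], 2)
#>                     R1   T1   T2   R2
#> stable_decreasing 0.42 0.39 0.29 0.47
#> stable_increasing 0.03 0.32 0.31 0.11
```

The pipeline recovers the planted three-system layout (exactly four
decreasing and four increasing regions; one cohort's stable core can
split into a few extra components) and this single cohort's group mean
stable–decreasing coupling falls from ~0.42 at rest toward ~0.29 during
the demanding task and returns, while the stable–increasing coupling
rises from ~0.03 to ~0.31 — the two-way reorganization signature.
Averaged over 25 cohorts (as `scripts/acceptance.R` does) the
trajectories land within a few hundredths of the calibrated values.

The full study workflow lives in `analysis/01_simulate_cohort.R`
through `analysis/07_ica_validation.R`: cohort simulation (with motion
exclusions in R2), preprocessing, seed connectivity, region detection,
system dynamics, brain–behaviour correlation, and the ICA arm, writing
tables under `results/`.

See `vignettes/dmn-dynamics-methods.Rmd` for the generator's model,
calibration choices and limitations.

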