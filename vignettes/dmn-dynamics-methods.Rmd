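---
title: "Methods: simulating and measuring task-dependent DMN reorganization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring task-dependent DMN reorganization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis this package implements

The package studies the dynamic reorganization of the default-mode
network (DMN) across a four-stage steady-state design: a pre-task
resting run (R1), a relaxed-pace visual classification task (T1), a
speeded version of the same task (T2), and a post-task resting run
(R2).  Each run is 150 volumes at TR = 2 s.  The analysis chain is:

1. **Temporal preprocessing** per run: drop the first 10 volumes,
   smooth spatially at 8 mm FWHM, band-pass 0.008–0.08 Hz (zero-phase
   Butterworth), regress nuisance series (white-matter mean, CSF mean,
   global mean, six rigid-body motion parameters), and censor motion
   frames: a frame is flagged when **both** the frame-wise global-signal
   change (≥ 0.5% BOLD) and the frame-wise displacement (≥ 0.5 mm,
   Power-style with a 50 mm rotation lever arm) reach threshold; the
   flagged frame, the one before and the two after are removed.  A run
   losing more than 60 volumes is excluded.
2. **Seed connectivity**: the mean time course of an 8 mm sphere at the
   posterior cingulate coordinate (0, −53, 26) is correlated with every
   brain voxel, Fisher-Z transformed, and tested at the group level with
   a one-sample t-test and Benjamini–Yekutieli FDR at q = 0.05.  The
   positive-t significant voxels form each state's network map.
3. **Region detection**: within the union of the four state maps, a
   one-way repeated-measures ANOVA (subject as blocking factor,
   df = 3, 3(n−1)) detects state-dependent voxels (FDR q = 0.05),
   clusters larger than 5 voxels survive, and a retrospective paired
   t-test of mean(T1, T2) vs mean(R1, R2) — FDR-corrected across the
   tested voxels, as in the source analyses — labels voxels
   *decreasing* or *increasing*.  *Stable* voxels appear in all four
   maps and show no ANOVA change; both stable components and classified
   regions must exceed 5 voxels, so degenerate one-voxel "regions"
   never enter the system-level averages.
4. **System dynamics**: per subject and state, mean functional
   connectivity within and between the stable/decreasing/increasing
   systems (unweighted average over region pairs, reported on the r
   scale, tested on the Fisher-Z scale), with paired t-tests between
   consecutive states and the R1–R2 null check under one FDR family.
5. **Brain–behavior**: per-subject dFC = meanFC(task) − meanFC(R1) for
   the stable–decreasing and stable–increasing couplings, correlated
   with mean RT and accuracy; percentile bootstrap CIs from 1000
   resamples; FDR across the panel.
6. **ICA validation arm**: group spatial ICA (subject-wise temporal
   PCA, concatenation, group PCA, infomax with logistic nonlinearity;
   model order by the MDL criterion on the covariance eigen-spectrum),
   DMN component selection by template matching (mean z inside minus
   outside the template), GICA back-projection to subject maps, and the
   identical region statistics on those maps.  Two practical notes: MDL
   assumes a flat noise floor and saturates on band-passed data, so the
   workflow fixes the order in the low twenties there; and the region
   statistics require components that are comparable across states, so
   the workflow runs one decomposition over all subject-state runs
   rather than four separate ones.  On the default cohort the
   cross-arm spatial correlation is 0.55–0.75 per state and the
   increasing-region overlap is near-perfect, while decreasing regions
   are poorly visible to the spatial DMN component once they decouple —
   an asymmetry the seed arm does not share.

No scan data accompanies the design, so all of this runs on a synthetic
cohort generator that is itself a first-class, tested module.

# The generator

## Planted structure

The default scenario plants fourteen signal regions on a 24×36×24 grid
of 3 mm voxels: six stable DMN regions (the seed-bearing posterior
cingulate block of 5³ voxels plus five 4³ blocks), four decreasing and
four increasing 4³ regions.  Every region's voxels share one latent
signal; the latent inter-region correlation matrix per state is built
from block-level targets:

| block | R1 | T1 | T2 | R2 |
|---|---|---|---|---|
| stable–decreasing | 0.43 | 0.35 | 0.24 | 0.45 |
| stable–increasing | 0.05 | 0.30 | 0.34 | 0.03 |
| within stable | 0.60 | 0.60 | 0.60 | 0.60 |
| within decreasing | 0.46 | 0.36 | 0.26 | 0.46 |
| within increasing | 0.12 | 0.32 | 0.36 | 0.10 |
| decreasing–increasing | 0.02 | 0.10 | 0.12 | 0.02 |

The two between-system rows are the group values reported for this
design; the within-system and decreasing–increasing rows are not
printed anywhere at this precision and are completed with a plausible
profile (tightly coupled stable core; the changing systems
desynchronize/synchronize in step with their coupling to it).

Pair-level values are **not** uniform within a block: the seed region's
pairs with the changing systems modulate more strongly across states
(`seed_gain = 2.5`), the remaining stable regions correspondingly less
(gain 0.7), with the block average equal to the printed trajectory
exactly.  This mirrors the reported pair-level pattern — seed-to-
increasing couplings start near zero or negative at rest and rise
sharply during task, while parietal stable regions change less — and it
is what makes voxel-level detection feasible at all: with 140
band-limited frames the sampling SD of a single pair's Fisher-Z is
≈ 0.175, so a uniform-trajectory block (state spread ≈ 0.09) would give
a per-region ANOVA noncentrality of ~13 and coin-flip detection, while
the seed-amplified trajectory (spread ≈ 0.22 for seed pairs) detects
essentially always.

Region names (PCC, MPFC, IPL, LTC, PCS, ANG, VER, I/IFC, ACC, MCC) are
conventional anatomical shorthand used purely as labels; the layout is
schematic.  Regions are segregated by grid lane so that the 8 mm
smoothing kernel can never mix systems (cross-system gaps ≥ 5 voxels)
or merge same-class clusters (same-class gaps ≥ 10): during
development, layouts with 3-voxel gaps produced biases up to +0.3 in
detected-region system means because smoothing shells straddling two
regions carry both latents.

## Subject heterogeneity

Each subject draws one Fisher-Z offset per block shared by all four
states (`subject_sd_common = 0.12`) plus independent state-specific
offsets (`subject_sd = 0.12`).  The split is a calibration choice (the
reported SEMs pin only the total): the common part models trait-like
connectivity differences and is absorbed by the subject blocking factor
of the ANOVA; the state part carries the between-subject variation in
task modulation that the behaviour stage couples to.  Simulated
group-level SEMs come out at 0.035–0.045, bracketing the reported
0.028–0.047.  Perturbed matrices are mapped through `tanh`, and
eigenvalues are floored in the rare case a perturbation leaves the PSD
cone.

## Noise model and why GSR is neutral here

Voxel time series are built as: latent signal (amplitude 1.5 in planted
regions) + AR(1) voxel noise (φ = 0.4, SD 0.6) + a 0.003 Hz drift of
amplitude 1 (removed by the band-pass) + a baseline of 1000 + motion
artifacts.  Three further structured components make the nuisance
regression meaningful:

* WM and CSF compartments carry their own latent signals, so those
  regressors remove something real.
* Twenty small background-network patches (2³ voxels, amplitude 2,
  mutually correlated at 0.5) occupy lattice slots away from the
  planted regions; they give the ICA arm non-trivial structure to find.
* A **diffuse field** (amplitude 1.2) covers all brain voxels at
  Chebyshev distance > 3 from every signal region (and outside WM/CSF).

The field is what makes global-signal regression approximately neutral.
The global mean unavoidably contains a weighted mix of the planted
latents; regressing it out projects that mix — which correlates ~0.7
with every region latent — out of every region series, deflating
measured correlations by up to ~0.15 when the global mean contains
little else.  Real brains dilute this with widespread non-DMN activity;
the field plays that role.  Its amplitude was calibrated by simulation
so the end-to-end pipeline measures the planted correlations without
systematic shift (residual bias below ~0.02 on every block/state cell);
the moat keeps the field, and its smoothed tail, out of the regions and
their detection shells, which is also why the *measured* time courses
contain no field and GSR cannot re-introduce shared variance into them.
A uniform "physiological" component covering the regions themselves was
tried and rejected: its post-GSR residual is shared between the
(lower-amplitude) detected shells and inflates between-system
correlations.

## Motion and scrubbing

Motion traces are slow random walks (SD 0.01 mm/frame).  Spikes are
Poisson-placed at the configured per-state rate, at least 5 frames
apart: the translation steps by 1.2 mm and stays, and the image takes a
one-frame global intensity impulse of 1.5% of baseline, so each spike
exceeds **both** censoring thresholds at exactly one frame and the
removal arithmetic (4 frames per isolated flag) is unambiguous.  The
default scenario uses rate 0 everywhere — in the emulated study no
volumes were removed in R1/T1/T2 — while the analysis scripts raise the
R2 rate to reproduce the situation where a few subjects lose more than
60 volumes there and drop out of the four-state analysis only.

## Behaviour coupling

RT and accuracy are generated as
`state mean + SD · (ρ·z + sqrt(1−ρ²)·ε)` with `z` the standardized
latent dFC of the relevant coupling (decreasing↔RT, increasing↔
accuracy), population means/SDs taken from the reported group values
(RT 1864/1310 ms, accuracy 97.8/94.5%), and accuracy clipped to
[0, 100].  The generative couplings are `rt = (0.82, 0.79)` and
`accuracy = (0.65, 0.79)` for (T1, T2).  These are deliberately higher
than the target sample correlations (≈ 0.60/0.57 and 0.49/0.59):
pipeline-estimated dFC is the difference of two band-limited
correlation estimates and carries estimation noise that attenuates the
measured association by a factor of 0.72–0.77 (measured by simulation
at n = 19), with another 2% lost to accuracy clipping.  The couplings
are calibrated so that the *measured* brain–behaviour correlations land
at the reported effect sizes — the generator emulates the observed
study, and the observable in the study is the measured correlation.

# Numerical choices

* Band-pass: 4-pole Butterworth applied forward–backward on
  mirror-padded series; the whole operation (including mean removal) is
  one cached frames×frames linear operator, so wide voxel matrices are
  filtered in a single BLAS call, and the band-pass + nuisance
  regression compose into one operator (identical to the sequential
  steps to ~1e−12; a test asserts this).
* Smoothing: separable Gaussian with half-sample reflective boundaries
  (symmetric operator; preserves both image mass and constants), in
  compiled code with an R-matrix reference implementation used as the
  test oracle.
* Correlation clipping at |r| = 1 − 1e−7 before `atanh`.
* AR(1) generation via a cached Toeplitz square-root operator, exact in
  the stationary distribution; identical per-channel filtering
  preserves latent cross-correlations exactly.
* FDR: Benjamini–Yekutieli step-up everywhere by default
  (Benjamini–Hochberg selectable); implemented via `p.adjust` and
  tested against a brute-force step-up oracle.
* Cluster connectivity: 26-neighbourhood by default, 6 selectable.
* RM-ANOVA: no sphericity correction by default; Greenhouse–Geisser
  optional.
* Infomax: natural-gradient updates with logistic nonlinearity over
  voxel minibatches, learning-rate annealing, convergence at weight
  change < 1e−6; deterministic under a fixed seed.
* Reproducibility: every stochastic stage derives its seed from the
  top-level seed through a Lehmer-style hash, so identical
  (scenario, seed) reproduce a cohort bit-for-bit.

# Problem sizes used by the packaged experiments

The replicated experiments run at the sizes the package documents as
its study conditions: 25 end-to-end cohorts of 16 subjects for the
system-level calibration and region-count checks, 6 cohorts for the
no-dynamics null, and 200 fast-path cohorts of 19 subjects for the
behaviour stage.  A 16-subject cohort takes roughly half a minute on
one core; the fast path (region-level time courses only) takes about a
second per cohort.

# What passing tests do and do not show

The generator reproduces the *statistical* structure the analysis
assumes — state-dependent latent correlations, between-subject
heterogeneity, censoring-relevant motion spikes, behaviour coupled to
connectivity change — on an idealized geometry.  It does not emulate
anatomical shapes, spatial normalization error, slice timing,
task-locked hemodynamic responses, state-dependent SNR changes, or
non-stationary physiological noise.  Passing the calibrated-recovery
tests shows the pipeline measures planted structure without material
bias under these conditions; it cannot certify behaviour on real scans.

Two further limitations are worth stating plainly:

* Detected regions are dilated relative to the planted blocks (Jaccard
  ≈ 0.25–0.45 against the planted voxels, coverage ≈ 1.0): 8 mm
  smoothing genuinely spreads the latent signal beyond the planted
  support and the detection step correctly finds it there.  The
  detected extent reflects the smoothed signal, not a defect, but
  strict voxel-set agreement with the *unsmoothed* truth is not
  achievable at this kernel-to-region size ratio.
* The per-replicate "dissociation" check on the behaviour panel (all
  four planted couplings FDR-significant and the four crossed ones not,
  within one cohort) has essentially no power at n = 19 and sample
  correlations of 0.49–0.60: even uncorrected per-test power is ≈ 0.6
  for the weakest coupling, so the joint event occurs in well under
  half of replicates (about 1% under the pooled BY family).  The
  package reports the panel faithfully; the corresponding acceptance
  expectation fails, and the mean-recovery checks are the meaningful
  validation of this stage.
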