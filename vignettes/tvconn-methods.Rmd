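---
title: "Methods: estimating and testing within-block FC dynamics"
author: "tvconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and testing within-block FC dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvconn)
```

## The problem

Psychophysiological-interaction and DCM-style analyses of block-designed
fMRI treat functional connectivity (FC) as constant within a task block.
With a sub-second repetition time (TR = 0.645 s) a 20 s block contains
roughly 31 samples, enough to estimate correlation *as a function of
time* and ask whether the coupling itself is dynamic. `tvconn`
implements that estimation chain and the group-level tests around it,
plus a synthetic cohort generator with exactly known ground truth so the
whole chain is verifiable without access to any scanner data.

## Model and procedure

### Temporal skeleton

A `TaskDesign` records block onsets, block duration, TR, acquired
volumes and the number of initial volumes discarded before analysis.
`visualBlockDesign()` is the default: onsets at 20, 60, 100 s, 20 s
blocks, 240 volumes of which the first 14 (≈9 s) are discarded. All
epoching uses the retained grid; relative time 0 is the sample nearest
each onset, and all windows are half-open `[lo, hi)` in seconds.

### Preprocessing

The retained ROI series are residualized in a *single joint* ordinary
least-squares regression against: the task regressor (unit boxcar
convolved with the canonical double-gamma HRF — peak delay 6 s,
undershoot delay 16 s, dispersions 1 s, ratio 6, length 32 s,
peak-normalized), the six motion parameters and their backward-difference
derivatives, optional white-matter/CSF summary columns, and a
discrete-cosine drift basis with all frequencies below 1/128 Hz
(`floor(2·n·TR·f)` columns; 2 columns at n = 226). A single joint
regression is used because sequential partial regressions are
order-dependent and no ordering is canonical. The drift basis is part of
the joint model rather than a separate filter for the same reason.
Afterwards a second-order Butterworth low-pass at 0.75 Hz is applied
forward and backward (zero phase, DC gain 1).

Removing the task-evoked component before windowed correlation is not
optional cosmetics: correlation is a statistic for stochastic signals,
and a deterministic evoked response shared by two ROIs produces
time-locked windowed-correlation modulation that has nothing to do with
coupling. `taskRemovalDemo()` quantifies this on a constant-correlation
cohort as the ratio of the cycle-averaged group-mean TVCC range without
vs with task removal; the acceptance script recomputes it on every run.
BOLD-level analyses, in contrast, keep the evoked response (the task
regressor is excluded from their nuisance set) — there the evoked
response *is* the signal.

### TVCC

At every sample t the time-varying correlation coefficient is the
weighted Pearson correlation over a window centered at t with Gaussian
weights

\[ K_h(u) = \exp(-u^2/h), \qquad |u| \le \lfloor h/2 \rfloor , \]

u in samples and h the window size in samples. Two readings of this
kernel are possible (`exp(-u²/h)` vs `exp(-u²/h²)`); the package takes
the printed form literally — the same h appears in the support condition
in samples, so at h = 24 the edge weight is `exp(-144/24) = exp(-6)`.
The support is the symmetric 25-point set |u| ≤ 12: a 24-sample window
cannot be centered symmetrically, and phase neutrality wins the tie.
`windowSamples()` converts a window length in seconds to h by
truncation, reproducing the canonical pairing 16 s ↔ 24 samples at
TR 0.645 s (and 21 / 27 samples for the 14 / 18 s sensitivity windows).

At the series edges the window is truncated and the remaining weights
renormalized — never padded or reflected, because padding invents data
and the sub-period analysis exists precisely to validate conclusions
free of window-edge bias. Samples whose truncated window holds fewer
than 3 points, or where a windowed variance vanishes, are flagged
invalid (`NA`) rather than raising an error. r is clipped into
[−1, 1] and Fisher-transformed, z = atanh(r), after clipping |r| to
1 − 10⁻⁷; every downstream group statistic operates on z.

### Group statistics

Per subject, BOLD, TVCC-z or slope values are averaged element-wise
across the three cycles on the relative-time grid [−10, +30) s
(offsets −15…+46). Then:

* **Baseline tests** — each subject's baseline is the mean over
  [−10, 0) (15 samples); each post-onset sample gets a two-tailed
  one-sample t-test of (value − baseline) across subjects.
* **Trend tests** — per-subject point-wise slopes from a centered 16 s
  rectangular window (offsets |m| ≤ 12, truncated at epoch edges,
  ≥3 samples required), tested against zero.
* **Sub-period validation** — plain (unweighted) Pearson correlations in
  PRE [−10,0), EARLY [0,10), LATE [10,20), POST [20,30) s per cycle,
  Fisher-z, cycle means, then a one-way repeated-measures ANOVA
  (within-subject SS partition, df = (k−1), (n−1)(k−1), no sphericity
  correction by default; Greenhouse–Geisser available) and, only when
  the ANOVA p < 0.05, paired t-tests between the three adjacent
  sub-period pairs.

Multiple testing uses the classical Benjamini–Hochberg step-up. The
correction *family* is a genuine design choice the analysis description
leaves open; the package uses the narrowest reading consistent with a
per-panel presentation: point-wise tests are corrected across the tested
samples of one signal (one ROI or one pair), and post-hoc tests across
the three adjacent comparisons of one pair. Zero-variance samples yield
t = 0, p = 1 with a `degenerate` flag so degenerate synthetic inputs
complete instead of erroring.

## The synthetic generator

`simulateCohort()` draws, per subject (with an RNG stream derived
deterministically from `(seed, subject index)` so cohorts are
reproducible under parallel or out-of-order generation):

* **Activation** — amplitude ~ N(mean, sd²) per activated ROI (defaults
  1 ± 0.2 in units of the noise SD), times boxcar⊗HRF.
* **Correlated noise** — unit-variance AR(1) processes (φ = 0.3).
  For each prescribed pair trajectory, a shared AR process `c_p` is
  mixed into both members: ROI i receives
  `Σ_p s_p √λ_p(t) c_p + √(1 − Σ_p λ_p(t)) e_i` with λ_p(t) = |ρ_p(t)|
  and the sign carried by the second member. Because the shared and
  unique processes have identical autocovariance, the instantaneous
  correlation equals ρ_p(t) exactly, even as λ varies — the reason this
  construction was chosen over per-sample Cholesky mixing of AR output,
  which distorts the target under AR smoothing. The construction spends
  Σ|ρ| of each ROI's unit variance on shared components, so the summed
  |ρ| over trajectories touching one ROI must stay below 1; the
  generator validates this and errors otherwise.
* **Drift** — quadratic with N(0,1) coefficients scaled by
  `driftAmplitude` (default 0.5): enough to exercise the drift basis
  without modeling scanner physics.
* **Motion** — Gaussian random walks (step SD 0.02 mm / 0.02°). These
  are nuisance theater: realistic enough to exercise the regression and
  framewise-displacement paths, not an artifact model.

ρ(t) is piecewise linear between knots with flat extrapolation;
between-subject variability adds a level shift (SD 0.05, clipped to
±0.95) per trajectory. The default scenario prescribes, for the two
within-hemisphere visual pairs LMOG–LFuG and RMOG–RFuG, a drop from 0.6
to 0.2 ramping down over 5–12 s after each onset, holding through block
offset, and recovering by +27 s. Two choices here are deliberately the
package's own: **(a)** the magnitude of the drop — the source experiment
reports the effect only graphically, so 0.6 → 0.2 is a package default,
chosen once as a moderate, realistic inter-areal change (Δz ≈ 0.49);
**(b)** the two *disjoint* pairs rather than all four MOG×FuG pairs —
two 0.6-level trajectories through one ROI would demand
Σ|ρ| = 1.2 > 1 of its variance, which the shared-component construction
cannot represent.

`embedInVolumes()` places a cohort into 4D NIfTI volumes (every voxel
in an 8 mm sphere carries its ROI's series plus i.i.d. voxel noise) to
exercise the extraction path: sphere membership is voxel-center-within-
radius (inclusive) in world mm, mean extraction is the voxel average,
and the first-eigenvariate variant regresses the nuisance matrix from
every voxel, takes the first left singular vector, scales it to the
ROI's RMS amplitude (u₁s₁/√n_vox) and sign-aligns it with the ROI-mean
residual (tie-break: the first voxel's residual). The eigenvariate
conventions are stated contracts, not reconstructions: the analysis
description names the procedure but not its sign/scale conventions.
Both extraction methods are exposed; real analyses describe using both
the ROI average and the adjusted first eigenvariate, and which fed the
published connectivity numbers is ambiguous, so neither is privileged.

### What the generator does *not* emulate

No biophysical forward model (Balloon/neural-mass), no spatial
structure beyond the ROI spheres, no physiological (cardiac/
respiratory) noise, no slice-timing or motion *artifacts* (motion
tables exist but do not corrupt the series). Passing tests therefore
show that the estimation chain recovers known trajectory dynamics under
realistic noise levels — they do not certify behavior under real-scanner
artifact structure.

## Numerical and edge-case choices

* Backward differences (first row 0) for motion derivatives; framewise
  displacement is the mean absolute backward difference of the three
  translations (mm) and, separately, the three rotations (degrees,
  converted from radians when declared). The cited FD literature admits
  summed-vs-mean and radius-conversion variants; the mean-absolute form
  is a documented package choice, and the per-frame series keeps frame 1
  at 0 with summary means over the differenced frames.
* The 0.75 Hz low-pass sits at 97 % of Nyquist at TR 0.645 s. Where it
  is unrealizable (cutoff ≥ Nyquist) the filter warns and passes data
  through unchanged rather than erroring, so designs with longer TR
  still run. The zero-phase pass uses odd-reflection padding at both
  ends so filter transients decay in the padding, giving exact DC gain
  on constant input.
* The 1/128 Hz drift basis is included in the connectivity nuisance set
  by default (switchable via `highpass = FALSE`): whether the published
  analysis applied it to the FC series or only inside the activation
  GLM is ambiguous, and including it is the conservative reading.
* Residualization checks rank via pivoted QR and names the collinear
  columns; it is idempotent to machine precision.
* `fisherZ(±1)` is finite by construction (clip at 1 − 10⁻⁷), which
  gives identical, comparable values for degenerate perfectly-correlated
  windows instead of infinities.

## Validation problem sizes

The shipped tests validate the chain at the cohort size of the emulated
experiment (n = 20): 100 replicate cohorts for the recovery/power study
(ANOVA p < 0.05 with an FDR-significant EARLY > LATE drop, and an
FDR-significant negative within-block slope, each required in ≥ 80 % of
replicates), 500 constant-ρ cohorts for null calibration (per-sample
uncorrected type-I error within 0.05 ± 0.02; cohorts with any
FDR-rejected FC sample ≤ 10 %), Monte-Carlo correlation calibration at
200 subjects (±0.02), and 10⁶-draw oracles for the mixing construction.
`scripts/acceptance.R` re-runs the replicate studies from scratch at
these sizes and writes the measured rates as JSON.

## Known limitations

* The windowed estimator is biased near change points (a 16 s window
  mixes pre- and post-onset samples for the first ~8 s); the sub-period
  analysis is the window-free check, and conclusions should rest on
  both.
* BH-FDR is applied per signal; no cluster-based or permutation
  correction over time, no mixed-effects modeling, no between-group
  comparisons.
* Only the two-process mixing family of ground truths is supported;
  trajectories whose summed |ρ| through one ROI reaches 1 are
  unrepresentable by construction.
* Real-data use assumes spatially preprocessed, co-registered volumes;
  the package deliberately contains no registration, smoothing or
  slice-timing machinery.
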