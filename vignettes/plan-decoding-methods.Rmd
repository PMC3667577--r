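---
title: "Decoding delayed movement plans from event-related BOLD: models and methods"
author: "planMVPA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding delayed movement plans from event-related BOLD: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planMVPA)
```

## The scientific problem

In a slow event-related delayed-movement experiment, a subject previews a
target object (Preview, 6 s), hears an instruction naming the upcoming
action and holds the plan in mind through a fixed delay (Plan, 12 s),
executes the movement on a go cue (Execute), and rests while the BOLD
response returns to baseline (ITI, 14 s).  With two actions (grasp vs
reach) crossed with two effectors (the hand alone, or reverse tongs whose
operating kinematics are opposite to the hand's; the effector is fixed
within a run and alternates across runs), multi-voxel pattern analysis of
the *delay-period* activity can ask three questions per region of
interest:

1. do voxel patterns predict the upcoming action with the hand
   (within-hand decoding)?
2. with the tool (within-tool decoding)?
3. does a classifier trained on hand trials transfer to tool trials and
   vice versa (cross-effector decoding), which would indicate a shared,
   effector-independent code for the action goal rather than for the
   muscle-level kinematics?

The pattern of answers yields a categorical *coding profile* per region:
hand-specific, tool-specific, effector-specific for both effectors,
effector-independent, execute-only, or null.

`planMVPA` implements this analysis end to end — epoching, decoding,
group inference, profile classification — together with a synthetic BOLD
generator that plants each coding scheme by construction, so every stage
can be verified against ground truth without any external data.

## The generative model

Each run is simulated at TR = 2 s.  A trial occupies 17 volumes
(34 s / 2 s): Preview volumes 1–3, Plan volumes 4–9, Execute volume 10,
ITI volumes 11–17.  Runs carry a 2-volume lead-in before the first trial
onset so that the first trial's baseline volume ("volume −1") exists;
the default run is therefore 2 + 20 × 17 = 342 volumes.

Per voxel, the neural (pre-hemodynamic) signal is the sum of

* a **task response** common to all voxels and conditions —
  0.5 %SC during Preview, 1.0 %SC during Plan, 1.5 %SC during Execute —
  which makes the region visible to the localizing contrast without
  biasing any between-condition comparison;
* a **condition pattern**: a fraction of voxels (default 0.5) is
  informative; each informative voxel carries a signed half-amplitude
  (+a for grasp, −a for reach, sign drawn per voxel) during the volumes
  its coding scheme declares informative:
  Plan-through-Execute for the four planning schemes, the Execute volume
  for `execute_only`, and the first two Plan volumes for
  `cue_transient` (the auditory-instruction transient).
  Shared-code schemes (`effector_independent`, `cue_transient`) reuse
  one pattern for both effectors; separate-code schemes
  (`effector_specific_both`, `execute_only`) draw independent patterns
  per effector; `hand_specific`/`tool_specific` plant a pattern for one
  effector only.

The neural signal is convolved with a Boynton gamma HRF
(shape n = 3, time constant τ = 1.2 s, zero delay, unit sum — the
canonical parameter values for this kernel), added to a baseline of 100,
and corrupted by i.i.d. Gaussian noise (SD in %SC units, default 1.0),
optionally AR(1) in time, plus an optional low-frequency cosine drift so
the high-pass stage has something real to remove.

Two generator-specific numerical choices matter:

* **Kernel truncation.** The generator truncates the HRF at 14 s support
  (~0.2% of kernel mass).  One trial's evoked response then decays
  exactly to zero before the next trial's baseline volume, making
  adjacent trials exactly independent — the generative counterpart of
  the design argument that test data a full trial length apart are
  uncoupled.  The analysis-side default kernel keeps a finer 1e-6
  truncation.
* **Counterbalancing.** Condition orders are drawn per run and repaired
  by local swaps until, pooled across all runs of one effector, the four
  ordered first-order transition counts are uniform within ±1 — each
  trial type preceded and followed equally often by every other.

Inter-subject variability is exposed as an optional multiplicative
amplitude jitter (`subjectJitterSd`), off by default: no published value
constrains its magnitude, so the reference conditions do not claim one.

## The analysis pipeline

**Epoching.** Each trial window spans its baseline volume −1 through
volume 17.  Every voxel is converted to percent signal change relative
to its own baseline volume: PSC(v) = 100·(x(v) − x(−1))/x(−1).  Volume
indexing within the trial is 1-based (volume 1 = trial onset); file-level
indices are 0-based.  Error-flagged trials are excluded before epoching
(in GLMs they become predictors of no interest instead).  The **plan
epoch** is the average pattern over volumes 8–9, the final 4 s of the
delay before the go cue.

**Rescaling.** At each timepoint, every voxel is mapped affinely onto
[−1, +1] across all trials of the pairwise comparison (constant voxels
map to 0).  This replicates the conventional preparation of SVM inputs;
because the scaling uses all trials, it technically peeks at test trials'
minima/maxima.  A leakage-safe variant (`rescaleWithinTrainFold = TRUE`)
fits the scaling on each fold's training trials only; with the default
reference parameters the two variants differ by well under one accuracy
point, and the default replicates the conventional procedure.  Scaling is
fit across the session (all runs of the effector), the natural reading of
"across all trials"; per-run scaling is not offered.

**Decoding.** A soft-margin linear SVM (libSVM via `e1071`, fixed
C = 1, no internal scaling) is evaluated by leave-one-trial-pair-out
cross-validation: trials of the two classes are paired by within-class
chronological rank (first grasp with first reach, …) — a deterministic,
order-respecting rule chosen because the pairing is otherwise
unconstrained; each fold holds out one pair, trains on the rest, and
accuracy is correct test predictions over 2N.  After error exclusion,
surplus trials of the larger class stay in every training set and are
never tested, so all data are used while only pairs are scored.
Cross-effector decoding instead uses a single train-and-test iteration
per direction on all available data, and reports the mean of the two
directions (both retained for asymmetry checks).  An exact decision-value
tie is assigned to the lexicographically first class — determinism over
randomness.  Voxel weights come from one single-shot fit on all trials,
signed so that positive means grasp-preferring; the top-k fingerprint
selects the k voxels with the largest absolute weight across comparisons
(ties to the lowest index) and normalizes magnitudes to a maximum of 1
within each comparison, preserving signs.

**Group inference.** Per-subject accuracies at every timepoint and for
the plan epoch are tested against 50% chance with a two-tailed one-sample
t test, with Benjamini–Hochberg FDR at q ≤ 0.05 over one family per ROI:
all tests performed within that ROI (every decoded timepoint × the three
comparisons, plus the plan-epoch cells).  Families are never pooled
across ROIs.  Zero-variance accuracies follow a declared convention:
mean exactly at chance gives t = 0, p = 1; mean off chance with zero
variance is treated as maximally significant (p set to the smallest
positive double).  A two-level permutation test is available for
plan-epoch accuracies: labels are fully permuted within each subject
(class counts preserved), the decoding is re-run, the across-subject mean
forms the group null, and p uses the add-one estimator
(1 + #{null ≥ observed})/(1 + n~perm~), n~perm~ defaulting to 1000 —
reaching p < 0.001 therefore needs at least 999 permutations.  The exact
permutation scheme is a declared default (the approach it follows is
conventional two-level randomization), not a published prescription.
Repeated-measures comparisons among the three accuracies use a one-way
within-subject ANOVA with Greenhouse–Geisser ε computed from the
double-centered sample covariance (bounded in [1/(k−1), 1]), fractional
GG-adjusted degrees of freedom, and FDR-corrected paired follow-up
t tests.

**Profile classification.** The per-ROI label is a hard decision table
on FDR flags: hand only → hand-specific; tool only → tool-specific;
hand and tool without cross-transfer → effector-specific-both; all
three → effector-independent; neither during planning but significant
after movement onset → execute-only; otherwise null.  "After movement
onset" means any FDR-flagged within-effector cell at volumes 10–17,
a window that covers the hemodynamic lag of the execute response.
Borderline "trend" p values do not enter the table — only flags do.

## ROI localization

The GLM module builds one unit-height boxcar per (condition, phase) —
3 Preview volumes, 6 Plan volumes, 1 Execute volume; the ITI is
unmodelled so betas are relative to ITI baseline — convolves them with
the HRF, adds per-run intercepts and drift confounds, and fits ordinary
least squares per voxel.  The localizing contrast pools all conditions:
+1 on every Plan and Execute column, −2 on every Preview column, so the
weights sum to zero and selection cannot bias any later between-condition
comparison (verified empirically: ROI selection on null data followed by
decoding stays at chance).  Conjunction maps are Boolean ANDs of
individually thresholded t maps (t ≥ 3).  ROI selection takes all
supra-threshold voxels whose centers fall in a 15 mm cube around a seed,
keeps face-connected (6-connectivity) clusters of at least a configurable
volume (113.5 mm³ — about 5 voxels at 3 mm isotropic — mirrors the
average minimum cluster size this kind of correction produces), and
control ROIs drop the threshold to t = 0, keeping all positive voxels
with no cluster filter.  The published per-subject Monte-Carlo cluster
correction itself is not reproduced — only a fixed minimum-size
threshold is offered, with the connectivity rule declared here because
the original correction does not state one.

**High-pass filtering** projects out a Fourier harmonic basis
(sine + cosine pairs at 1..5 cycles per run).  The span of this basis
contains every phase-shifted drift cosine up to the cutoff, so such
drifts are removed exactly, while the run mean and higher exact
harmonics pass unchanged; the same basis enters GLM designs as drift
confounds, keeping filtering and fitting consistent.  (A one-sided DCT
basis of the same order removes arbitrary-phase drifts only
approximately, which is why the harmonic-pair parameterisation was
chosen.)

## Reference conditions and calibrated constants

Three reference configurations (`referenceConfig()`) fix the conditions
used by the verification suites; their constants were calibrated once
during development and then frozen:

| profile | scheme | amplitude (%SC) | design |
|---|---|---|---|
| `null` | null | 0 | 13 subjects, 4 runs/effector, 10 trials/condition/run, 54 voxels, noise SD 1.0 |
| `weak_signal` | effector_specific_both | 0.098 | same full design |
| `recovery` | any | 1.2 | 8 subjects, 1 run/effector, 10 trials/condition, 24 voxels |

* 0.098 %SC on half of 54 voxels yields across-subject mean plan-epoch
  decoding near 55% — the magnitude typical of single-trial plan
  decoding, where accuracies are statistically reliable yet far from
  ceiling.
* 1.2 %SC is a clearly-detectable effect for the reduced recovery
  design, chosen so that misclassification of a planted profile is
  dominated by the irreducible ~5% familywise false-positive rate of
  the q = 0.05 decision table, not by misses.
* The temporal-specificity suite uses 13 subjects on the reduced design
  with `execute_only` at 1.2 %SC and `cue_transient` at 0.5 %SC; the
  weaker cue amplitude keeps the mid-Plan transient detectable while its
  hemodynamic tail at the plan epoch (≈13% of the peak response) stays
  within noise, reproducing the dissociation expected of an
  auditory-cue region — information mid-delay, none in the pre-movement
  epoch.

The Monte-Carlo suites run on deliberately reduced designs (fewer runs,
voxels, or subjects per replicate, as tabulated above) so that hundreds
of full pipeline replicates stay cheap; the full 13-subject, 8-run,
54-voxel design is exercised by the chance- and weak-signal-calibration
checks and the acceptance script.

## What the generator does and does not emulate

The generator reproduces the statistical structure the analysis assumes:
slow event-related timing, HRF-convolved sustained and transient
responses, multivoxel condition patterns of controlled amplitude and
sparsity, per-run effector constancy, counterbalanced orders, error
trials, drift, and AR(1) noise.  It does not emulate spatial
autocorrelation of noise, motion or physiological artifacts, field
inhomogeneity, anatomical variability, or voxel-level tuning
correlations — so passing tests certify the *pipeline's* statistical
behavior (calibration, specificity, type-I control, recoverability), not
performance on real scanner data.  Real-data mode (NIfTI + events.tsv +
ROI JSON) applies the identical analysis path to externally produced
inputs.

## Degenerate inputs and tie-breaks

* Constant feature columns rescale to 0 rather than ±∞.
* Decision-value ties go to the lexicographically first class.
* Zero-variance group accuracies follow the declared t-test convention.
* Identical rmANOVA columns give F = 0, p = 1, ε = 1.
* Empty ROI selections warn and return an empty ROI; the caller decides.
* Fewer than 3 trials per class refuses to cross-validate; fewer than
  2 trials per condition refuses to counterbalance.

## Known limitations

* The cluster correction is a fixed minimum-size threshold; the original
  per-subject Monte-Carlo procedure is not reproduced.
* Voxelwise group random-effects mapping (for display) is out of scope;
  "RFX" fitting is realized as per-run OLS with subject-level
  aggregation at the accuracy stage.
* The permutation test re-runs the full decoding per permutation and is
  accordingly expensive at published permutation counts.
* Decoding accuracies on discrete fold counts are granular
  (1/2N steps); group t tests on 4–6 subjects inherit that
  discreteness, which slightly widens their attained type-I band.
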