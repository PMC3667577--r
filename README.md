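# planMVPA

Time-resolved multi-voxel pattern analysis (MVPA) of slow event-related
fMRI delayed-movement experiments, for researchers who want to decode
*planned* actions — not executed ones — from delay-period BOLD activity
and to characterize, per region of interest, whether that planning code
is specific to an effector (the hand, or a tool with opposite operating
kinematics) or independent of it.

## What it computes

Trials follow a Preview (6 s) → Plan (12 s) → Execute → ITI (14 s)
structure at TR = 2 s, with two actions (grasp vs reach) crossed with
two effectors (hand vs tool; effector fixed per run).  For each ROI the
pipeline computes:

- **Percent-signal-change trial tensors**: each voxel's time course in
  every trial window, expressed relative to the baseline volume
  immediately preceding trial onset, with error trials excluded and
  per-voxel rescaling to [−1, +1];
- **Time-resolved and plan-epoch decoding**: leave-one-trial-pair-out
  cross-validated linear SVM accuracy (libSVM, C = 1) at every
  within-trial volume and for the averaged final two Plan volumes
  (volumes 8–9);
- **Cross-effector generalization**: classifiers trained on all hand
  trials tested on all tool trials and vice versa, the two directions
  averaged — above-chance transfer indicates an effector-independent
  code for the action goal;
- **Group inference**: two-tailed t tests of accuracy against 50%
  chance, Benjamini–Hochberg FDR (q ≤ 0.05) over one family per ROI,
  optional two-level permutation nulls, Greenhouse–Geisser-corrected
  repeated-measures ANOVA with FDR-corrected paired follow-ups;
- **Voxel-weight maps and top-10 fingerprints** from single-shot fits,
  signed grasp-positive;
- **Coding profiles**: a hard decision table mapping the FDR flags to
  one of `hand_specific`, `tool_specific`, `effector_specific_both`,
  `effector_independent`, `execute_only`, `null`.

A synthetic BOLD generator plants each of these coding schemes by
construction (HRF-convolved condition patterns plus Gaussian/AR(1)
noise and drift), so every stage is verifiable against ground truth
without any data download, and a boxcar-GLM localizer module
(contrast/conjunction t maps, 15-mm-cube ROI selection with cluster
correction, control ROIs) covers ROI definition for both the motor
paradigm and block-design category localizers.

## Worked example

Simulate a small group with three planted regional codes and run the
full pipeline (plan-epoch volumes 8–9 plus two execute-phase volumes):

```r
library(planMVPA)

cfg <- generatorConfig(
  nSubjects = 4, nRunsPerEffector = 2, trialsPerCondition = 8,
  nVoxels = 24, seed = 42,
  roiSchemes = list(
    pIPS = codingScheme("effector_independent", 1.2, 0.5),
    SPOC = codingScheme("hand_specific",        1.2, 0.5),
    SS   = codingScheme("execute_only",         1.2, 0.5)))

rep <- runPipeline(cfg, timepoints = c(8, 9, 11, 12))
for (p in rep$profiles) show(p)
#> CodingProfile 'pIPS': effector_independent  [hand=TRUE tool=TRUE cross=TRUE execute=TRUE]
#> CodingProfile 'SPOC': hand_specific  [hand=TRUE tool=FALSE cross=FALSE execute=TRUE]
#> CodingProfile 'SS': execute_only  [hand=FALSE tool=FALSE cross=FALSE execute=TRUE]
```

Each profile row is the categorical summary of that region's decoding:
`pIPS` (planted with one shared pattern for hand and tool) decodes both
effectors *and* transfers across them; `SPOC` (hand-only pattern)
decodes the hand but neither the tool nor across effectors; `SS`
(execute-only pattern) is silent throughout planning and decodes only
after movement onset.  The per-cell group statistics behind these flags:

```r
subset(groupStats(rep$results$pIPS), timepoint == "plan")
#>      comparison timepoint meanAccuracy   t             p fdrSignificant
#>       hand_GvsR      plan            1 Inf 2.225074e-308           TRUE
#>       tool_GvsR      plan            1 Inf 2.225074e-308           TRUE
#>  cross_effector      plan            1 Inf 2.225074e-308           TRUE
```

(at this deliberately strong 1.2 %SC amplitude all four subjects decode
perfectly, so the zero-variance t convention applies; the
`weak_signal` reference configuration instead produces the ~55%
accuracies typical of real plan decoding).  `runPipeline(cfg, outDir =
"results/")` additionally writes tidy TSVs, a JSON profile report, and
accuracy-vs-time plots with the 50% chance line.

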