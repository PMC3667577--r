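Package: planMVPA
Title: Multi-Voxel Pattern Decoding of Delayed Movement Plans from
    Event-Related fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for time-resolved multi-voxel pattern
    analysis (MVPA) of slow event-related BOLD data from delayed-movement
    experiments: percent-signal-change trial epoching, leave-one-trial-
    pair-out linear support vector machine decoding at every within-trial
    volume and for the pre-movement plan epoch, bidirectional cross-
    effector generalization, group t-tests against chance with false
    discovery rate control, permutation nulls, Greenhouse-Geisser
    corrected repeated-measures ANOVA, voxel-weight maps and top-k weight
    fingerprints, and a categorical coding-profile classifier per region
    of interest.  Includes a synthetic BOLD generator that plants known
    per-ROI coding schemes (hand-specific, tool-specific, effector-
    specific, effector-independent, execute-only, cue-transient) so every
    stage of the analysis is verifiable without any external data, plus
    boxcar GLM localization of regions of interest with contrast and
    conjunction t-maps, cube-constrained voxel selection, and cluster
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    e1071,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
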