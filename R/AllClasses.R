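#' @import methods
NULL

#' Trial phase timing template
#'
#' Timing of one slow event-related trial: an object Preview phase, a
#' delay (Plan) phase initiated by an auditory instruction, a brief
#' Execute phase, and an inter-trial interval (ITI) that lets the BOLD
#' response return to baseline.  All durations are in seconds and must be
#' multiples of the repetition time (TR).
#'
#' @slot previewS seconds of object preview (default 6)
#' @slot planS seconds of movement-planning delay (default 12)
#' @slot executeS seconds of movement execution (default 2)
#' @slot itiS seconds of inter-trial interval (default 14)
#' @slot trS repetition time in seconds (default 2)
#' @export
setClass("PhaseTemplate",
  representation(previewS = "numeric", planS = "numeric",
                 executeS = "numeric", itiS = "numeric", trS = "numeric"),
  prototype(previewS = 6, planS = 12, executeS = 2, itiS = 14, trS = 2))

setValidity("PhaseTemplate", function(object) {
  d <- c(object@previewS, object@planS, object@executeS, object@itiS)
  if (any(d <= 0) || object@trS <= 0)
    return("all phase durations and the TR must be positive")
  if (any(abs(d / object@trS - round(d / object@trS)) > 1e-8))
    return("every phase duration must be a whole number of TRs")
  TRUE
})

#' Construct a trial phase template
#'
#' @param previewS,planS,executeS,itiS,trS phase durations and TR, seconds.
#' @return a \linkS4class{PhaseTemplate}
#' @examples
#' pt <- phaseTemplate()
#' volumesPerTrial(pt)  # 17 for the 34-s trial at TR 2 s
#' @export
phaseTemplate <- function(previewS = 6, planS = 12, executeS = 2,
                          itiS = 14, trS = 2) {
  new("PhaseTemplate", previewS = previewS, planS = planS,
      executeS = executeS, itiS = itiS, trS = trS)
}

#' @describeIn phaseTemplate total trial duration in seconds
#' @param x a \code{PhaseTemplate}
#' @export
trialDuration <- function(x) x@previewS + x@planS + x@executeS + x@itiS

#' @describeIn phaseTemplate number of imaging volumes per trial
#' @export
volumesPerTrial <- function(x) as.integer(round(trialDuration(x) / x@trS))

#' Within-trial volume indices of each phase (1-based, volume 1 = trial onset)
#'
#' @param x a \linkS4class{PhaseTemplate}
#' @return named list of integer vectors: \code{preview}, \code{plan},
#'   \code{execute}, \code{iti}
#' @export
phaseVolumes <- function(x) {
  np <- x@previewS / x@trS; nl <- x@planS / x@trS
  ne <- x@executeS / x@trS; ni <- x@itiS / x@trS
  # Execute is modelled as a single movement volume; the remainder of the
  # illuminated period plus the return movement falls into the ITI span.
  ne <- max(1L, as.integer(round(ne / 2)))
  start <- cumsum(c(1, np, nl, ne))
  list(preview = seq.int(start[1], length.out = np),
       plan    = seq.int(start[2], length.out = nl),
       execute = seq.int(start[3], length.out = ne),
       iti     = seq.int(start[4], volumesPerTrial(x)))
}

## ---------------------------------------------------------------------------

.schemeNames <- c("null", "hand_specific", "tool_specific",
                  "effector_specific_both", "effector_independent",
                  "execute_only", "cue_transient")

#' Planted coding scheme for a simulated region of interest
#'
#' Describes which task conditions a simulated voxel population can
#' discriminate, and when.  The taxonomy mirrors the summary profiles an
#' MVPA study of delayed hand and tool actions reports per region:
#' regions that decode planned actions of the hand only, of the tool
#' only, of both effectors with separate codes, of both with a shared
#' (effector-independent) code, only after movement onset, or only during
#' a brief auditory-cue transient.
#'
#' @slot name one of \code{"null"}, \code{"hand_specific"},
#'   \code{"tool_specific"}, \code{"effector_specific_both"},
#'   \code{"effector_independent"}, \code{"execute_only"},
#'   \code{"cue_transient"}
#' @slot patternAmplitude half-separation of the grasp vs reach voxel
#'   patterns, in percent-signal-change units (>= 0)
#' @slot informativeFraction fraction of voxels carrying condition
#'   information, in [0, 1]
#' @slot transientVols duration, in volumes, of the cue transient (used by
#'   \code{cue_transient} only)
#' @export
setClass("CodingScheme",
  representation(name = "character", patternAmplitude = "numeric",
                 informativeFraction = "numeric", transientVols = "integer"),
  prototype(name = "null", patternAmplitude = 0,
            informativeFraction = 0.5, transientVols = 2L))

setValidity("CodingScheme", function(object) {
  if (!(object@name %in% .schemeNames))
    return(sprintf("unknown scheme '%s'", object@name))
  if (length(object@patternAmplitude) != 1 || object@patternAmplitude < 0)
    return("patternAmplitude must be a single non-negative number")
  if (object@informativeFraction < 0 || object@informativeFraction > 1)
    return("informativeFraction must lie in [0, 1]")
  if (object@transientVols < 1L)
    return("transientVols must be >= 1")
  TRUE
})

#' Construct a coding scheme
#'
#' @param name scheme name; see \linkS4class{CodingScheme}
#' @param patternAmplitude pattern half-separation in %SC units
#' @param informativeFraction fraction of informative voxels
#' @param transientVols cue-transient duration in volumes
#' @return a \linkS4class{CodingScheme}
#' @export
codingScheme <- function(name, patternAmplitude = 0,
                         informativeFraction = 0.5, transientVols = 2L) {
  new("CodingScheme", name = name, patternAmplitude = patternAmplitude,
      informativeFraction = informativeFraction,
      transientVols = as.integer(transientVols))
}

setMethod("show", "CodingScheme", function(object) {
  cat(sprintf("CodingScheme '%s': amplitude %.3g %%SC, %.0f%% informative voxels\n",
              object@name, object@patternAmplitude,
              100 * object@informativeFraction))
})

## ---------------------------------------------------------------------------

#' One functional run of BOLD data
#'
#' A voxel-by-volume matrix of simulated or measured BOLD signal for one
#' run, together with its TR, the effector in use throughout the run
#' (effector is constant within a run), and, for synthetic data, the
#' planted ground truth.
#'
#' @slot data numeric matrix, voxels x volumes
#' @slot trS repetition time, seconds
#' @slot effector \code{"hand"} or \code{"tool"}
#' @slot runId integer run index
#' @slot groundTruth list of planted patterns and amplitudes (may be empty)
#' @export
setClass("RunTimeseries",
  representation(data = "matrix", trS = "numeric", effector = "character",
                 runId = "integer", groundTruth = "list"),
  prototype(trS = 2, effector = "hand", runId = 1L, groundTruth = list()))

setValidity("RunTimeseries", function(object) {
  if (anyNA(object@data)) return("BOLD data must not contain NA/NaN")
  if (!(object@effector %in% c("hand", "tool")))
    return("effector must be 'hand' or 'tool'")
  if (object@trS <= 0) return("trS must be positive")
  TRUE
})

setMethod("show", "RunTimeseries", function(object) {
  cat(sprintf("RunTimeseries: run %d (%s), %d voxels x %d volumes, TR %gs\n",
              object@runId, object@effector, nrow(object@data),
              ncol(object@data), object@trS))
})

#' @rdname RunTimeseries-class
#' @param x a \code{RunTimeseries}
#' @export
timeseriesData <- function(x) x@data

#' @rdname RunTimeseries-class
#' @export
effector <- function(x) x@effector

#' @rdname RunTimeseries-class
#' @export
runId <- function(x) x@runId

## ---------------------------------------------------------------------------

#' A multi-run synthetic dataset for one subject
#'
#' @slot runs named list; one element per ROI, each a list of
#'   \linkS4class{RunTimeseries} across runs
#' @slot schedule data.frame of trial events (onset_s, effector, action,
#'   run_id, error)
#' @slot config the generator configuration used
#' @export
setClass("SyntheticDataset",
  representation(runs = "list", schedule = "data.frame", config = "list"))

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset: %d ROI(s) x %d runs, %d trials\n",
              length(object@runs),
              length(object@runs[[1]]),
              nrow(object@schedule)))
  cat("  ROIs:", paste(names(object@runs), collapse = ", "), "\n")
})

#' @rdname SyntheticDataset-class
#' @param x a \code{SyntheticDataset}
#' @export
datasetSchedule <- function(x) x@schedule

#' @rdname SyntheticDataset-class
#' @param roi ROI name
#' @export
datasetRuns <- function(x, roi = NULL) {
  if (is.null(roi)) x@runs else x@runs[[roi]]
}

## ---------------------------------------------------------------------------

#' Trials x volumes x voxels percent-signal-change tensor
#'
#' Holds epoched single-trial time courses in percent signal change
#' relative to the baseline volume immediately preceding each trial
#' ("volume -1"), plus per-trial metadata.  Error trials are excluded
#' before epoching.
#'
#' @slot values numeric array trials x withinTrialVolumes x voxels
#' @slot info data.frame with one row per trial (action, effector,
#'   run_id, onset_s)
#' @slot trS repetition time, seconds
#' @export
setClass("TrialTensor",
  representation(values = "array", info = "data.frame", trS = "numeric"))

setValidity("TrialTensor", function(object) {
  if (length(dim(object@values)) != 3)
    return("values must be a 3-d array (trials x volumes x voxels)")
  if (nrow(object@info) != dim(object@values)[1])
    return("trial metadata rows must match the number of trials")
  TRUE
})

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("TrialTensor: %d trials x %d volumes x %d voxels (%%SC)\n",
              d[1], d[2], d[3]))
})

#' @rdname TrialTensor-class
#' @param x a \code{TrialTensor}
#' @export
tensorValues <- function(x) x@values

#' @rdname TrialTensor-class
#' @export
trialInfo <- function(x) x@info

## ---------------------------------------------------------------------------

#' Trials x voxels classifier input at one timepoint or epoch
#'
#' @slot values numeric matrix trials x voxels
#' @slot labels factor of class labels (action: grasp/reach)
#' @slot timepoint tag: a within-trial volume index as character, or
#'   \code{"plan-epoch"}
#' @slot rescaled logical; TRUE once per-voxel [-1, +1] rescaling applied
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", labels = "factor",
                 timepoint = "character", rescaled = "logical"),
  prototype(rescaled = FALSE))

setValidity("FeatureMatrix", function(object) {
  if (nrow(object@values) != length(object@labels))
    return("one label per trial row is required")
  TRUE
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix [%s]: %d trials x %d voxels%s\n",
              object@timepoint, nrow(object@values), ncol(object@values),
              if (object@rescaled) ", rescaled to [-1, +1]" else ""))
})

#' @rdname FeatureMatrix-class
#' @param x a \code{FeatureMatrix}
#' @export
featureValues <- function(x) x@values

#' @rdname FeatureMatrix-class
#' @export
featureLabels <- function(x) x@labels

## ---------------------------------------------------------------------------

#' Ordinary least squares GLM fit for one run
#'
#' @slot betas predictors x voxels matrix of regression coefficients
#' @slot residVar per-voxel residual variance (denominator dof-adjusted)
#' @slot dof residual degrees of freedom (volumes - rank of design)
#' @slot design the design matrix used
#' @slot xtxInv (X'X)^-1 for contrast variance computation
#' @export
setClass("GlmFit",
  representation(betas = "matrix", residVar = "numeric", dof = "numeric",
                 design = "matrix", xtxInv = "matrix"))

setMethod("show", "GlmFit", function(object) {
  cat(sprintf("GlmFit: %d predictors x %d voxels, %d residual dof\n",
              nrow(object@betas), ncol(object@betas), object@dof))
})

#' @rdname GlmFit-class
#' @param x a \code{GlmFit}
#' @export
glmBetas <- function(x) x@betas

#' @rdname GlmFit-class
#' @export
glmDof <- function(x) x@dof

## ---------------------------------------------------------------------------

#' A selected region of interest on a voxel lattice
#'
#' @slot name ROI name
#' @slot seedMm seed coordinate in mm (length 3)
#' @slot voxelIndices linear indices of member voxels (1-based)
#' @slot tValues per-member-voxel t statistics
#' @slot params selection parameters (t threshold, cube edge mm,
#'   minimum cluster mm^3, voxel size mm)
#' @export
setClass("RoiDefinition",
  representation(name = "character", seedMm = "numeric",
                 voxelIndices = "integer", tValues = "numeric",
                 params = "list"))

setValidity("RoiDefinition", function(object) {
  if (length(object@voxelIndices) != length(object@tValues))
    return("one t value per member voxel is required")
  TRUE
})

setMethod("show", "RoiDefinition", function(object) {
  cat(sprintf("RoiDefinition '%s': %d voxels\n", object@name,
              length(object@voxelIndices)))
})

#' @rdname RoiDefinition-class
#' @param x a \code{RoiDefinition}
#' @export
roiVoxels <- function(x) x@voxelIndices

#' @rdname RoiDefinition-class
#' @export
roiTValues <- function(x) x@tValues

## ---------------------------------------------------------------------------

.comparisons <- c("hand_GvsR", "tool_GvsR", "cross_effector")

#' Per-ROI decoding accuracies with group statistics
#'
#' @slot roi ROI name
#' @slot accuracies array subjects x comparisons x timepoints; the
#'   timepoint axis holds the within-trial volumes ("t1".."t17") followed
#'   by "plan" for the plan-epoch
#' @slot groupStats data.frame: comparison, timepoint, meanAccuracy, t, p,
#'   fdrSignificant
#' @export
setClass("DecodingResult",
  representation(roi = "character", accuracies = "array",
                 groupStats = "data.frame"))

setValidity("DecodingResult", function(object) {
  a <- object@accuracies
  if (length(dim(a)) != 3)
    return("accuracies must be subjects x comparisons x timepoints")
  if (any(a < 0 | a > 1, na.rm = TRUE))
    return("accuracies must lie in [0, 1]")
  TRUE
})

setMethod("show", "DecodingResult", function(object) {
  d <- dim(object@accuracies)
  sig <- object@groupStats[object@groupStats$fdrSignificant, , drop = FALSE]
  cat(sprintf("DecodingResult '%s': %d subjects x %d comparisons x %d timepoints\n",
              object@roi, d[1], d[2], d[3]))
  cat(sprintf("  %d FDR-significant cell(s) at the declared family\n", nrow(sig)))
})

#' @rdname DecodingResult-class
#' @param x a \code{DecodingResult}
#' @export
accuracies <- function(x) x@accuracies

#' @rdname DecodingResult-class
#' @export
groupStats <- function(x) x@groupStats

## ---------------------------------------------------------------------------

.profileLabels <- c("hand_specific", "tool_specific",
                    "effector_specific_both", "effector_independent",
                    "execute_only", "null")

#' Categorical coding profile of one ROI
#'
#' The per-region summary label derived from which pairwise comparisons
#' decode significantly during the plan epoch and whether decoding is
#' present after movement onset.
#'
#' @slot roi ROI name
#' @slot label one of \code{hand_specific}, \code{tool_specific},
#'   \code{effector_specific_both}, \code{effector_independent},
#'   \code{execute_only}, \code{null}
#' @slot evidence named logical vector: handSig, toolSig, crossSig,
#'   executeSig
#' @export
setClass("CodingProfile",
  representation(roi = "character", label = "character",
                 evidence = "logical"))

setValidity("CodingProfile", function(object) {
  if (!(object@label %in% .profileLabels))
    return(sprintf("unknown profile label '%s'", object@label))
  need <- c("handSig", "toolSig", "crossSig", "executeSig")
  if (!all(need %in% names(object@evidence)))
    return("evidence must contain handSig, toolSig, crossSig, executeSig")
  TRUE
})

setMethod("show", "CodingProfile", function(object) {
  ev <- object@evidence
  cat(sprintf("CodingProfile '%s': %s  [hand=%s tool=%s cross=%s execute=%s]\n",
              object@roi, object@label, ev["handSig"], ev["toolSig"],
              ev["crossSig"], ev["executeSig"]))
})

#' @rdname CodingProfile-class
#' @param x a \code{CodingProfile}
#' @export
profileLabel <- function(x) x@label

#' @rdname CodingProfile-class
#' @export
profileEvidence <- function(x) x@evidence
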