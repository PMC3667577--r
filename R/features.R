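#' Drop error-flagged trials from a schedule
#'
#' Trials flagged as performance errors are removed from all downstream
#' feature extraction and decoding (in the GLM they are modelled as
#' predictors of no interest instead; see
#' \code{\link{buildDesignMatrix}}).
#'
#' @param schedule schedule data.frame with an \code{error} column
#' @return the schedule without error trials
#' @export
excludeErrorTrials <- function(schedule) {
  schedule[!schedule$error, , drop = FALSE]
}

#' High-pass filter a run
#'
#' Projects the per-run Fourier harmonic basis (see
#' \code{\link{harmonicBasis}}) up to \code{cyclesPerRun} out of every
#' voxel's time course.  The run mean is preserved; drifts at or below
#' the cutoff are removed exactly; oscillations at higher harmonic
#' frequencies pass unchanged.
#'
#' @param run a \linkS4class{RunTimeseries}
#' @param cyclesPerRun cutoff in cycles per run (default 5)
#' @return the filtered \linkS4class{RunTimeseries}
#' @export
highpassFilter <- function(run, cyclesPerRun = 5) {
  y <- run@data
  nVols <- ncol(y)
  if (cyclesPerRun >= nVols / 2)
    stop("highpassFilter: cutoff must be below the Nyquist frequency")
  if (nVols <= 2 * cyclesPerRun)
    stop("highpassFilter: run too short for this cutoff")
  B <- harmonicBasis(nVols, cyclesPerRun)
  # least-squares projection of each voxel's time course onto the basis
  coef <- t(qr.coef(qr(B), t(y)))
  run@data <- y - coef %*% t(B)
  run
}

#' Epoch a run into single-trial percent-signal-change time courses
#'
#' For every non-error trial, extracts the window from the baseline
#' volume ("volume -1", the volume immediately preceding trial onset)
#' through the last ITI volume and converts each voxel to percent signal
#' change relative to its own baseline volume:
#' \deqn{PSC(v) = 100 (x(v) - x(base)) / x(base).}
#' The returned tensor's volume axis holds the baseline plane
#' (\code{"base"}, identically 0 by construction) followed by the
#' within-trial volumes \code{"t1"} .. \code{"t17"} (1-based, volume 1 =
#' trial onset; plan epoch = volumes 8-9 under the default template).
#'
#' @param run a \linkS4class{RunTimeseries}
#' @param schedule the session schedule (filtered to this run internally)
#' @param voxels optional voxel indices restricting the ROI
#' @param phase a \linkS4class{PhaseTemplate}
#' @return a \linkS4class{TrialTensor}
#' @export
epochTrials <- function(run, schedule, voxels = NULL,
                        phase = phaseTemplate()) {
  sch <- schedule[schedule$run_id == run@runId, , drop = FALSE]
  sch <- excludeErrorTrials(sch)
  if (nrow(sch) == 0) stop("epochTrials: no usable trials in this run")
  y <- run@data
  if (!is.null(voxels)) y <- y[voxels, , drop = FALSE]
  vpt <- volumesPerTrial(phase)
  nVox <- nrow(y)
  vals <- array(NA_real_, c(nrow(sch), vpt + 1L, nVox),
                dimnames = list(NULL, c("base", paste0("t", seq_len(vpt))),
                                NULL))
  for (i in seq_len(nrow(sch))) {
    onsetVol <- as.integer(round(sch$onset_s[i] / run@trS)) + 1L
    if (onsetVol - 1L < 1L)
      stop("epochTrials: the first trial has no baseline volume -1; ",
           "pad the schedule with lead-in volumes")
    if (onsetVol - 1L + vpt > ncol(y))
      stop("epochTrials: trial ", i, " extends past the end of the run")
    base <- y[, onsetVol - 1L]
    win <- y[, (onsetVol - 1L):(onsetVol - 1L + vpt), drop = FALSE]
    vals[i, , ] <- t(100 * (win - base) / base)
  }
  new("TrialTensor", values = vals,
      info = sch[, c("action", "effector", "run_id", "onset_s")],
      trS = run@trS)
}

#' Concatenate trial tensors across runs
#'
#' @param tensors list of \linkS4class{TrialTensor}s with matching volume
#'   and voxel axes
#' @return one \linkS4class{TrialTensor}
#' @export
bindTensors <- function(tensors) {
  stopifnot(length(tensors) > 0)
  d <- dim(tensors[[1]]@values)
  for (tn in tensors) stopifnot(all(dim(tn@values)[2:3] == d[2:3]))
  vals <- do.call(abind3, lapply(tensors, function(tn) tn@values))
  info <- do.call(rbind, lapply(tensors, function(tn) tn@info))
  new("TrialTensor", values = vals, info = info, trS = tensors[[1]]@trS)
}

# bind 3-d arrays along the first (trial) axis
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(NA_real_, c(sum(vapply(parts, function(p) dim(p)[1], 0L)),
                           d[2], d[3]),
               dimnames = list(NULL, dimnames(parts[[1]])[[2]], NULL))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Single-timepoint feature matrix
#'
#' The trials x voxels slice of the tensor at one within-trial volume.
#' Volume indexing is 1-based as in the trial timeline (volume 1 = trial
#' onset); index 0 addresses the baseline plane, which is identically 0.
#'
#' @param tensor a \linkS4class{TrialTensor}
#' @param volumeIndex within-trial volume, 0 (baseline) .. volumes/trial
#' @return a \linkS4class{FeatureMatrix} (not yet rescaled)
#' @export
timepointFeatures <- function(tensor, volumeIndex) {
  nv <- dim(tensor@values)[2] - 1L
  if (volumeIndex < 0 || volumeIndex > nv)
    stop("timepointFeatures: volume index must lie in 0..", nv)
  d <- dim(tensor@values)
  vals <- matrix(tensor@values[, volumeIndex + 1L, , drop = FALSE],
                 d[1], d[3])
  new("FeatureMatrix", values = vals,
      labels = factor(tensor@info$action),
      timepoint = as.character(volumeIndex))
}

#' Plan-epoch feature matrix
#'
#' The per-trial average pattern across the final two volumes of the
#' Plan phase (within-trial volumes 8-9 under the default template), the
#' 4-s window immediately preceding the cue to move.
#'
#' @param tensor a \linkS4class{TrialTensor}
#' @param volumes within-trial volumes averaged (default \code{8:9})
#' @return a \linkS4class{FeatureMatrix} (not yet rescaled)
#' @export
planEpochAverage <- function(tensor, volumes = 8:9) {
  nv <- dim(tensor@values)[2] - 1L
  if (any(volumes < 1 | volumes > nv))
    stop("planEpochAverage: volumes out of range")
  vals <- apply(tensor@values[, volumes + 1L, , drop = FALSE], c(1, 3), mean)
  new("FeatureMatrix", values = vals,
      labels = factor(tensor@info$action), timepoint = "plan-epoch")
}

#' Rescale features to [-1, +1] per voxel
#'
#' For each voxel column an affine map sends its minimum over trials to
#' -1 and its maximum to +1; constant columns map to 0.  Idempotent on
#' already-rescaled non-constant data.
#'
#' @param x a \linkS4class{FeatureMatrix} or plain trials x voxels matrix
#' @return same type as the input, rescaled
#' @export
rescaleFeatures <- function(x) {
  m <- if (is(x, "FeatureMatrix")) x@values else x
  if (nrow(m) < 2) stop("rescaleFeatures: at least 2 trials are required")
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1
  # 2*(x - lo)/rng - 1 maps lo -> -1 and hi -> +1 exactly, and IEEE
  # division keeps every intermediate quotient inside [0, 1]
  out <- 2 * sweep(sweep(m, 2, lo), 2, rng, "/") - 1
  out[, const] <- 0
  if (is(x, "FeatureMatrix")) {
    x@values <- out
    x@rescaled <- TRUE
    x
  } else out
}
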