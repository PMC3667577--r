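#' Generator configuration
#'
#' Bundles everything the synthetic BOLD generator needs: the session
#' design (subjects, runs, trials), the voxel population size, the noise
#' model, and a named list of per-ROI coding schemes.  Defaults reproduce
#' the study conditions of the delayed hand/tool movement design: 13
#' subjects, 4 runs per effector (8 total), 10 repetitions per condition
#' per run (20 trials/run), 34-s trials at TR 2 s, and 54 voxels per ROI
#' (a typical parieto-frontal ROI size).
#'
#' Noise is i.i.d. Gaussian per voxel per volume (SD in percent-signal-
#' change units of a baseline mean of 100), optionally AR(1) in time, with
#' an optional additive low-frequency cosine drift so the high-pass stage
#' has something to remove.  \code{subjectJitterSd} applies a
#' multiplicative, per-subject jitter to the pattern amplitude
#' (inter-subject variability knob; default off).
#'
#' @param nSubjects number of simulated subjects
#' @param nRunsPerEffector runs per effector
#' @param trialsPerCondition trials of each condition per run
#' @param nVoxels voxels per ROI
#' @param noiseSd Gaussian noise SD, %SC units
#' @param ar1Rho AR(1) autocorrelation of the noise (0 = white)
#' @param driftAmplitude amplitude of a low-frequency cosine drift, %SC
#' @param driftCycles cycles per run of the drift term
#' @param taskAmplitudes named numeric: evoked %SC response common to all
#'   voxels and conditions in the Preview, Plan and Execute phases (makes
#'   the region visible to the localizer contrast without biasing any
#'   condition comparison)
#' @param subjectJitterSd SD of the per-subject multiplicative amplitude
#'   jitter
#' @param errorRate probability a trial is flagged as a performance error
#' @param leadInVols baseline volumes before the first trial of each run
#' @param seed master seed
#' @param roiSchemes named list of \linkS4class{CodingScheme}s, one per ROI
#' @param phase a \linkS4class{PhaseTemplate}
#' @return a list of class \code{"generatorConfig"}
#' @export
generatorConfig <- function(nSubjects = 13, nRunsPerEffector = 4,
                            trialsPerCondition = 10, nVoxels = 54,
                            noiseSd = 1.0, ar1Rho = 0,
                            driftAmplitude = 0, driftCycles = 2,
                            taskAmplitudes = c(preview = 0.5, plan = 1.0,
                                               execute = 1.5),
                            subjectJitterSd = 0, errorRate = 0,
                            leadInVols = 2L, seed = 1,
                            roiSchemes = list(roi = codingScheme("null")),
                            phase = phaseTemplate()) {
  if (nSubjects < 1 || nRunsPerEffector < 1 || trialsPerCondition < 1 ||
      nVoxels < 1)
    stop("generatorConfig: all counts must be positive")
  if (noiseSd < 0) stop("generatorConfig: noiseSd must be non-negative")
  if (abs(ar1Rho) >= 1) stop("generatorConfig: |ar1Rho| must be < 1")
  stopifnot(all(c("preview", "plan", "execute") %in% names(taskAmplitudes)))
  for (s in roiSchemes) stopifnot(is(s, "CodingScheme"))
  structure(list(nSubjects = nSubjects,
                 nRunsPerEffector = nRunsPerEffector,
                 trialsPerCondition = trialsPerCondition,
                 nVoxels = nVoxels, noiseSd = noiseSd, ar1Rho = ar1Rho,
                 driftAmplitude = driftAmplitude, driftCycles = driftCycles,
                 taskAmplitudes = taskAmplitudes,
                 subjectJitterSd = subjectJitterSd, errorRate = errorRate,
                 leadInVols = as.integer(leadInVols), seed = seed,
                 roiSchemes = roiSchemes, phase = phase),
            class = "generatorConfig")
}

#' @export
print.generatorConfig <- function(x, ...) {
  cat(sprintf("generatorConfig: %d subjects, %d runs/effector x %d trials/condition, %d voxels\n",
              x$nSubjects, x$nRunsPerEffector, 2 * x$trialsPerCondition,
              x$nVoxels))
  cat(sprintf("  noise SD %g %%SC (AR1 rho %g), drift %g %%SC\n",
              x$noiseSd, x$ar1Rho, x$driftAmplitude))
  for (nm in names(x$roiSchemes))
    cat("  ROI", nm, "->", x$roiSchemes[[nm]]@name, "\n")
  invisible(x)
}

# Planted ground truth for one ROI and one subject: which voxels are
# informative, and the signed per-voxel grasp-vs-reach half-amplitudes for
# each effector.  Schemes with a shared code reuse one pattern for both
# effectors; schemes with separate codes draw independent sign patterns.
.makeGroundTruth <- function(scheme, nVoxels, amplitudeScale = 1) {
  nInf <- round(scheme@informativeFraction * nVoxels)
  idx <- if (nInf > 0) sort(sample.int(nVoxels, nInf)) else integer(0)
  a <- scheme@patternAmplitude * amplitudeScale
  draw <- function() {
    v <- numeric(nVoxels)
    if (length(idx) > 0) v[idx] <- a * sample(c(-1, 1), length(idx),
                                              replace = TRUE)
    v
  }
  zero <- numeric(nVoxels)
  pat <- switch(scheme@name,
    null = list(hand = zero, tool = zero),
    hand_specific = list(hand = draw(), tool = zero),
    tool_specific = list(hand = zero, tool = draw()),
    effector_specific_both = list(hand = draw(), tool = draw()),
    effector_independent = { p <- draw(); list(hand = p, tool = p) },
    execute_only = list(hand = draw(), tool = draw()),
    cue_transient = { p <- draw(); list(hand = p, tool = p) })
  window <- switch(scheme@name,
    execute_only = "execute",
    cue_transient = "cue",
    "plan_execute")
  list(scheme = scheme@name, informative = idx, pattern = pat,
       window = window, transientVols = scheme@transientVols)
}

# Within-trial volume indices during which the condition pattern is active.
.activeVolumes <- function(groundTruth, phase) {
  pv <- phaseVolumes(phase)
  switch(groundTruth$window,
    plan_execute = c(pv$plan, pv$execute),
    execute = pv$execute,
    cue = pv$plan[seq_len(min(groundTruth$transientVols, length(pv$plan)))])
}

#' Simulate one run of ROI BOLD data with a planted coding scheme
#'
#' Builds a neural (pre-hemodynamic) time series per voxel — a common
#' task-evoked response in every voxel during the Preview, Plan and
#' Execute phases plus, in the informative voxels, a signed
#' condition-specific amplitude during the volumes the scheme declares
#' informative — convolves it with the HRF, and adds baseline (100),
#' optional cosine drift, and Gaussian (optionally AR(1)) noise.
#'
#' @param scheme a \linkS4class{CodingScheme}
#' @param schedule schedule rows for this run (one effector)
#' @param hrf HRF kernel from \code{\link{boyntonHrf}}.  The generator
#'   default truncates the kernel at 14 s support (dropping ~0.2\% of its
#'   mass) so that one trial's evoked response has decayed exactly to
#'   zero before the next trial's baseline volume — the generative
#'   counterpart of the design argument that trials a full trial length
#'   apart are independent
#' @param nVoxels voxel count
#' @param noiseSd noise SD in %SC units
#' @param taskAmplitudes see \code{\link{generatorConfig}}
#' @param ar1Rho AR(1) noise autocorrelation
#' @param driftAmplitude,driftCycles cosine drift parameters
#' @param leadInVols baseline volumes before the first trial onset
#' @param phase a \linkS4class{PhaseTemplate}
#' @param groundTruth pre-drawn ground truth (from one subject's shared
#'   patterns); drawn from \code{scheme} if NULL
#' @param seed RNG seed (set if non-NULL)
#' @return a \linkS4class{RunTimeseries} carrying \code{groundTruth}
#' @export
simulateRoiTimeseries <- function(scheme, schedule,
                                  hrf = boyntonHrf(2, massTol = 2e-3),
                                  nVoxels = 54, noiseSd = 1.0,
                                  taskAmplitudes = c(preview = 0.5,
                                                     plan = 1.0,
                                                     execute = 1.5),
                                  ar1Rho = 0, driftAmplitude = 0,
                                  driftCycles = 2, leadInVols = 2L,
                                  phase = phaseTemplate(),
                                  groundTruth = NULL, seed = NULL) {
  if (noiseSd < 0) stop("simulateRoiTimeseries: noiseSd must be non-negative")
  if (length(unique(schedule$effector)) != 1)
    stop("simulateRoiTimeseries: a run holds exactly one effector")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(groundTruth)) groundTruth <- .makeGroundTruth(scheme, nVoxels)
  eff <- schedule$effector[1]
  vpt <- volumesPerTrial(phase)
  nTrials <- nrow(schedule)
  nVols <- as.integer(leadInVols + nTrials * vpt)
  pv <- phaseVolumes(phase)
  active <- .activeVolumes(groundTruth, phase)

  neural <- matrix(0, nVoxels, nVols)
  pat <- groundTruth$pattern[[eff]]
  for (i in seq_len(nTrials)) {
    onsetVol <- as.integer(round(schedule$onset_s[i] / phase@trS)) + 1L
    taskVols <- list(preview = onsetVol - 1L + pv$preview,
                     plan = onsetVol - 1L + pv$plan,
                     execute = onsetVol - 1L + pv$execute)
    for (ph in names(taskVols))
      neural[, taskVols[[ph]]] <- neural[, taskVols[[ph]]] +
        taskAmplitudes[[ph]]
    sgn <- if (schedule$action[i] == "grasp") 1 else -1
    av <- onsetVol - 1L + active
    av <- av[av >= 1 & av <= nVols]
    if (length(av) > 0)
      neural[, av] <- neural[, av] + sgn * pat
  }

  bold <- t(apply(neural, 1, convolveHrf, kernel = hrf)) + 100
  if (driftAmplitude > 0) {
    tt <- seq_len(nVols) - 1
    phases <- stats::runif(nVoxels, 0, 2 * pi)
    drift <- driftAmplitude *
      cos(outer(phases, 2 * pi * driftCycles * tt / nVols, "+"))
    bold <- bold + drift
  }
  if (noiseSd > 0) {
    eps <- matrix(stats::rnorm(nVoxels * nVols, sd = noiseSd), nVoxels, nVols)
    if (ar1Rho != 0) {
      for (tcol in 2:nVols)
        eps[, tcol] <- ar1Rho * eps[, tcol - 1] +
          sqrt(1 - ar1Rho^2) * eps[, tcol]
    }
    bold <- bold + eps
  }
  new("RunTimeseries", data = bold, trS = phase@trS, effector = eff,
      runId = as.integer(schedule$run_id[1]), groundTruth = groundTruth)
}

#' Simulate a full multi-run session for one subject
#'
#' Builds one counterbalanced schedule per session (runs alternate
#' effectors) and simulates every configured ROI against that shared
#' schedule.  All ROIs of a subject share the schedule; each ROI draws its
#' own voxel patterns once per subject and reuses them across runs, so a
#' scheme's cross-run (and, for shared-code schemes, cross-effector)
#' pattern structure is exactly what the scheme declares.  Deterministic
#' under a fixed seed.
#'
#' @param config a \code{\link{generatorConfig}}
#' @param subjectSeed integer seed for this subject
#' @return a \linkS4class{SyntheticDataset}
#' @examples
#' cfg <- generatorConfig(nRunsPerEffector = 1, trialsPerCondition = 3,
#'                        nVoxels = 8)
#' ds <- simulateSubject(cfg, subjectSeed = 1)
#' @export
simulateSubject <- function(config, subjectSeed = config$seed) {
  stopifnot(inherits(config, "generatorConfig"))
  set.seed(subjectSeed)
  schedSeed <- sample.int(.Machine$integer.max - 1, 1)
  schedule <- makeTrialSchedule(config$nRunsPerEffector,
                                config$trialsPerCondition,
                                phase = config$phase, seed = schedSeed,
                                leadInVols = config$leadInVols,
                                errorRate = config$errorRate)
  set.seed(subjectSeed + 1L)
  hrf <- boyntonHrf(config$phase@trS, massTol = 2e-3)
  jitter <- if (config$subjectJitterSd > 0)
    max(0, 1 + stats::rnorm(1, 0, config$subjectJitterSd)) else 1
  runs <- vector("list", length(config$roiSchemes))
  names(runs) <- names(config$roiSchemes)
  runIds <- sort(unique(schedule$run_id))
  for (roi in names(config$roiSchemes)) {
    scheme <- config$roiSchemes[[roi]]
    gt <- .makeGroundTruth(scheme, config$nVoxels, amplitudeScale = jitter)
    runSeeds <- sample.int(.Machine$integer.max - 1, length(runIds))
    runs[[roi]] <- lapply(seq_along(runIds), function(k) {
      simulateRoiTimeseries(scheme,
        schedule[schedule$run_id == runIds[k], , drop = FALSE],
        hrf = hrf, nVoxels = config$nVoxels, noiseSd = config$noiseSd,
        taskAmplitudes = config$taskAmplitudes, ar1Rho = config$ar1Rho,
        driftAmplitude = config$driftAmplitude,
        driftCycles = config$driftCycles, leadInVols = config$leadInVols,
        phase = config$phase, groundTruth = gt, seed = runSeeds[k])
    })
  }
  new("SyntheticDataset", runs = runs, schedule = schedule,
      config = unclass(config))
}

#' Simulate a block-design category localizer run
#'
#' Category-selective voxel populations respond more strongly during
#' 16-s blocks of their preferred stimulus category; all voxels give a
#' smaller common response to every stimulus block.  The block table
#' records onsets and labels.
#'
#' @param categories stimulus categories (>= 2)
#' @param nVoxPerCategory selective voxels per category
#' @param blocksPerCategory blocks of each category
#' @param blockS block duration, seconds (default 16)
#' @param baselineS fixation baseline at run start and end, seconds
#' @param selectivityAmplitude extra %SC response of a selective voxel to
#'   its preferred category (0 = no selectivity anywhere)
#' @param commonAmplitude %SC response of every voxel to every block
#' @param noiseSd Gaussian noise SD, %SC
#' @param trS TR, seconds
#' @param seed RNG seed
#' @return list with \code{run} (a \linkS4class{RunTimeseries};
#'   \code{groundTruth$preferred} maps voxels to categories) and
#'   \code{blocks} (data.frame: onset_s, duration_s, category)
#' @export
simulateBlockLocalizer <- function(categories = c("tools", "bodies",
                                                  "objects", "scrambled"),
                                   nVoxPerCategory = 12,
                                   blocksPerCategory = 6, blockS = 16,
                                   baselineS = 20,
                                   selectivityAmplitude = 1,
                                   commonAmplitude = 0.5, noiseSd = 1.0,
                                   trS = 2, seed = 1) {
  if (length(categories) < 2)
    stop("simulateBlockLocalizer: at least 2 stimulus categories required")
  set.seed(seed)
  blockVols <- as.integer(round(blockS / trS))
  baseVols <- as.integer(round(baselineS / trS))
  order <- sample(rep(categories, blocksPerCategory))
  nBlocks <- length(order)
  nVols <- 2L * baseVols + nBlocks * blockVols
  nVox <- nVoxPerCategory * length(categories)
  preferred <- rep(categories, each = nVoxPerCategory)

  blocks <- data.frame(
    onset_s = (baseVols + (seq_len(nBlocks) - 1) * blockVols) * trS,
    duration_s = blockS, category = order, stringsAsFactors = FALSE)

  neural <- matrix(0, nVox, nVols)
  for (b in seq_len(nBlocks)) {
    vols <- baseVols + (b - 1L) * blockVols + seq_len(blockVols)
    neural[, vols] <- neural[, vols] + commonAmplitude
    sel <- preferred == order[b]
    neural[sel, vols] <- neural[sel, vols] + selectivityAmplitude
  }
  hrf <- boyntonHrf(trS)
  bold <- t(apply(neural, 1, convolveHrf, kernel = hrf)) + 100
  if (noiseSd > 0)
    bold <- bold + matrix(stats::rnorm(nVox * nVols, sd = noiseSd),
                          nVox, nVols)
  run <- new("RunTimeseries", data = bold, trS = trS, effector = "hand",
             runId = 1L,
             groundTruth = list(preferred = preferred,
                                selectivityAmplitude = selectivityAmplitude))
  list(run = run, blocks = blocks)
}

#' Reference generator configurations
#'
#' Fixed, documented parameter sets used throughout the package's
#' verification suites:
#' \describe{
#'   \item{\code{"null"}}{the no-signal control: pattern amplitude 0,
#'     noise SD 1.0 %SC, 54 voxels, full design (4 runs/effector,
#'     10 trials/condition/run).  The full pipeline must decode at the
#'     50\% chance level on this configuration.}
#'   \item{\code{"weak_signal"}}{the weak-signal reference emulating
#'     realistic planning-related effect sizes: effector-specific
#'     patterns for both effectors, amplitude 0.098 %SC on half the
#'     voxels, noise SD 1.0 %SC, full design.  Plan-epoch decoding
#'     accuracy averages close to 55\%, the magnitude typical of
#'     single-trial plan decoding.}
#'   \item{\code{"recovery"}}{a clearly-detectable effect size on a
#'     reduced design (8 subjects, 1 run/effector, 10 trials/condition,
#'     24 voxels) used by the coding-profile recovery suite: amplitude
#'     1.2 %SC on half the voxels.}
#' }
#'
#' @param profile which reference set
#' @param schemeName coding scheme planted in the single ROI (default
#'   depends on the profile)
#' @param nSubjects number of subjects (default 13; the recovery profile
#'   defaults to 8)
#' @return a \code{\link{generatorConfig}}
#' @export
referenceConfig <- function(profile = c("weak_signal", "null", "recovery"),
                            schemeName = NULL, nSubjects = NULL) {
  profile <- match.arg(profile)
  switch(profile,
    null = generatorConfig(
      nSubjects = if (is.null(nSubjects)) 13 else nSubjects,
      roiSchemes = list(control = codingScheme(
        if (is.null(schemeName)) "null" else schemeName,
        patternAmplitude = 0))),
    weak_signal = generatorConfig(
      nSubjects = if (is.null(nSubjects)) 13 else nSubjects,
      roiSchemes = list(roi = codingScheme(
        if (is.null(schemeName)) "effector_specific_both" else schemeName,
        patternAmplitude = 0.098, informativeFraction = 0.5))),
    recovery = generatorConfig(
      nSubjects = if (is.null(nSubjects)) 8 else nSubjects,
      nRunsPerEffector = 1, trialsPerCondition = 10, nVoxels = 24,
      roiSchemes = list(roi = codingScheme(
        if (is.null(schemeName)) "effector_independent" else schemeName,
        patternAmplitude = if (identical(schemeName, "null")) 0 else 1.2,
        informativeFraction = 0.5))))
}
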