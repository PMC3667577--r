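#' Fourier harmonic drift basis
#'
#' Sine/cosine pairs at 1..\code{cycles} full cycles per run.  The span of
#' this basis contains every phase-shifted cosine drift up to the cutoff
#' frequency, so projecting it out removes such drifts exactly while
#' leaving the run mean (and all higher frequencies at exact harmonic
#' bins) untouched.
#'
#' @param nVolumes run length in volumes
#' @param cycles highest drift frequency, in cycles per run
#' @return matrix nVolumes x (2 * cycles)
#' @export
harmonicBasis <- function(nVolumes, cycles) {
  if (cycles < 1) return(matrix(numeric(0), nVolumes, 0))
  tt <- seq_len(nVolumes) - 1
  do.call(cbind, lapply(seq_len(cycles), function(k) {
    cbind(cos(2 * pi * k * tt / nVolumes), sin(2 * pi * k * tt / nVolumes))
  }))
}

#' Build a phase-aligned boxcar design matrix
#'
#' One unit-height boxcar per (condition, phase), aligned to the onset of
#' each phase and spanning that phase's volumes — 3 volumes for Preview,
#' 6 for Plan, 1 for Execute at the default 34-s trial — convolved with
#' the HRF.  The ITI is not modelled, so betas are defined relative to
#' ITI baseline.  A condition is one (effector, action) pair, so a
#' two-effector session yields 4 conditions x 3 phases = 12 task columns.
#' Confounds are per-run intercepts and, optionally, a per-run harmonic
#' drift basis.  Error trials, if present, are collected into predictors
#' of no interest (one column per phase) rather than their condition
#' columns.
#'
#' @param schedule schedule data.frame (possibly spanning several runs;
#'   rows of one run must share \code{run_id})
#' @param phase a \linkS4class{PhaseTemplate}
#' @param hrf HRF kernel
#' @param nVolumesPerRun volumes in each run
#' @param highpassCycles harmonic confounds up to this many cycles per
#'   run (0 = none)
#' @return list: \code{matrix} (volumes x predictors), \code{labels}
#'   (data.frame predictor, condition, phaseName, task flag),
#'   \code{taskColumns} (indices of task predictors)
#' @export
buildDesignMatrix <- function(schedule, phase = phaseTemplate(),
                              hrf = boyntonHrf(phase@trS),
                              nVolumesPerRun, highpassCycles = 0) {
  pv <- phaseVolumes(phase)
  phases <- c("preview", "plan", "execute")
  runIds <- sort(unique(schedule$run_id))
  nRuns <- length(runIds)
  totalVols <- nRuns * nVolumesPerRun

  conds <- unique(paste(schedule$effector, schedule$action, sep = "_"))
  conds <- sort(conds)
  hasErrors <- any(schedule$error)

  boxNames <- c(as.vector(outer(conds, phases, paste, sep = ".")),
                if (hasErrors) paste("error", phases, sep = "."))
  box <- matrix(0, totalVols, length(boxNames),
                dimnames = list(NULL, boxNames))
  for (i in seq_len(nrow(schedule))) {
    runPos <- match(schedule$run_id[i], runIds) - 1L
    onsetVol <- runPos * nVolumesPerRun +
      as.integer(round(schedule$onset_s[i] / phase@trS)) + 1L
    lastVol <- onsetVol - 1L + max(pv$execute)
    if (onsetVol < runPos * nVolumesPerRun + 1L ||
        lastVol > (runPos + 1L) * nVolumesPerRun)
      stop("buildDesignMatrix: trial ", i, " extends outside its run")
    cond <- if (schedule$error[i]) "error"
            else paste(schedule$effector[i], schedule$action[i], sep = "_")
    for (ph in phases) {
      col <- paste(cond, ph, sep = ".")
      if (!col %in% boxNames) next
      vols <- onsetVol - 1L + pv[[ph]]
      if (any(box[vols, col] != 0))
        stop("buildDesignMatrix: overlapping phases within a trial")
      box[vols, col] <- 1
    }
  }
  # error columns may be absent in practice; drop all-zero error columns
  keep <- colSums(abs(box)) > 0 | !startsWith(boxNames, "error.")
  box <- box[, keep, drop = FALSE]

  # convolve within each run
  X <- box
  for (r in seq_len(nRuns)) {
    rows <- (r - 1L) * nVolumesPerRun + seq_len(nVolumesPerRun)
    X[rows, ] <- apply(box[rows, , drop = FALSE], 2, convolveHrf,
                       kernel = hrf)
  }

  confNames <- character(0)
  conf <- matrix(numeric(0), totalVols, 0)
  for (r in seq_len(nRuns)) {
    rows <- (r - 1L) * nVolumesPerRun + seq_len(nVolumesPerRun)
    icpt <- numeric(totalVols); icpt[rows] <- 1
    cc <- icpt
    nms <- sprintf("run%d.intercept", runIds[r])
    if (highpassCycles > 0) {
      hb <- harmonicBasis(nVolumesPerRun, highpassCycles)
      hbFull <- matrix(0, totalVols, ncol(hb))
      hbFull[rows, ] <- hb
      cc <- cbind(cc, hbFull)
      nms <- c(nms, sprintf("run%d.drift%d", runIds[r], seq_len(ncol(hb))))
    }
    conf <- cbind(conf, cc)
    confNames <- c(confNames, nms)
  }
  colnames(conf) <- confNames
  full <- cbind(X, conf)
  nTask <- ncol(X)
  parts <- strsplit(colnames(X), ".", fixed = TRUE)
  labels <- data.frame(
    predictor = colnames(full),
    condition = c(vapply(parts, `[`, "", 1), rep(NA, ncol(conf))),
    phaseName = c(vapply(parts, `[`, "", 2), rep(NA, ncol(conf))),
    task = c(rep(TRUE, nTask), rep(FALSE, ncol(conf))),
    stringsAsFactors = FALSE)
  list(matrix = full, labels = labels, taskColumns = seq_len(nTask))
}

#' Fit a voxelwise ordinary least squares GLM
#'
#' @param y numeric matrix volumes x voxels, in percent signal change (or
#'   any units; betas are in the units of \code{y})
#' @param design output of \code{\link{buildDesignMatrix}}, or a plain
#'   design matrix
#' @return a \linkS4class{GlmFit}
#' @export
fitGlm <- function(y, design) {
  X <- if (is.list(design)) design$matrix else design
  if (is.vector(y)) y <- matrix(y, ncol = 1)
  if (nrow(X) != nrow(y))
    stop("fitGlm: design rows must match the number of volumes")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fitGlm: design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  betas <- qr.coef(qrX, y)
  res <- y - X %*% betas
  dof <- nrow(X) - qrX$rank
  residVar <- colSums(res^2) / dof
  new("GlmFit", betas = as.matrix(betas), residVar = residVar, dof = dof,
      design = X, xtxInv = chol2inv(qr.R(qrX))[order(qrX$pivot),
                                               order(qrX$pivot),
                                               drop = FALSE])
}

#' Contrast t map
#'
#' Per-voxel \eqn{t = c'\hat\beta / \sqrt{\hat\sigma^2 c'(X'X)^{-1}c}}.
#'
#' @param fit a \linkS4class{GlmFit}
#' @param weights contrast weight vector, one entry per predictor (in
#'   design-column order)
#' @return numeric vector of t values, one per voxel
#' @export
contrastTMap <- function(fit, weights) {
  if (length(weights) != nrow(fit@betas))
    stop("contrastTMap: weight vector length must equal the predictor count")
  num <- drop(crossprod(weights, fit@betas))
  cvc <- drop(t(weights) %*% fit@xtxInv %*% weights)
  num / sqrt(fit@residVar * cvc)
}

#' Movement-generation contrast weights
#'
#' The localizing contrast pools all conditions in every phase:
#' +1 on each Plan column, +1 on each Execute column and -2 on each
#' Preview column ([Plan & Execute > 2*Preview]), 0 on confounds, so the
#' weights sum to zero and the selection is not biased toward any
#' between-condition pattern difference.
#'
#' @param design output of \code{\link{buildDesignMatrix}}
#' @return numeric weight vector over all predictors
#' @export
motorContrastWeights <- function(design) {
  lb <- design$labels
  w <- numeric(nrow(lb))
  task <- lb$task & !is.na(lb$condition) & lb$condition != "error"
  w[task & lb$phaseName == "plan"] <- 1
  w[task & lb$phaseName == "execute"] <- 1
  w[task & lb$phaseName == "preview"] <- -2
  # keep the contrast balanced: scale preview so the weights sum to zero
  # even if a phase column was dropped (never the case in the full design)
  w
}

#' Conjunction of thresholded t maps (Boolean AND)
#'
#' A voxel survives only if every constituent t map reaches the threshold.
#'
#' @param tMaps list of numeric t maps over a common voxel space
#' @param threshold t threshold (default 3)
#' @return logical map
#' @export
conjunctionMask <- function(tMaps, threshold = 3) {
  if (length(tMaps) == 0)
    stop("conjunctionMask: at least one t map is required")
  n <- length(tMaps[[1]])
  for (m in tMaps) if (length(m) != n)
    stop("conjunctionMask: t maps must share one voxel space")
  Reduce(`&`, lapply(tMaps, function(m) m >= threshold))
}

# Face-connected (6-connectivity) components of a logical 3-d mask.
# Returns an integer array of component labels (0 = background).
.labelClusters <- function(mask) {
  dims <- dim(mask)
  labels <- array(0L, dims)
  nextLabel <- 0L
  offsets <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  idx <- which(mask)
  for (start in idx) {
    if (labels[start] != 0L) next
    nextLabel <- nextLabel + 1L
    queue <- start
    labels[start] <- nextLabel
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      pos <- arrayInd(cur, dims)
      for (o in seq_len(nrow(offsets))) {
        nb <- pos + offsets[o, ]
        if (any(nb < 1) || any(nb > dims)) next
        lin <- nb[1] + dims[1] * (nb[2] - 1 + dims[2] * (nb[3] - 1))
        if (mask[lin] && labels[lin] == 0L) {
          labels[lin] <- nextLabel
          queue <- c(queue, lin)
        }
      }
    }
  }
  labels
}

# voxel centers along one axis, mm (voxel i spans [(i-1)*s, i*s])
.voxelCenters <- function(n, voxelSizeMm) (seq_len(n) - 0.5) * voxelSizeMm

#' Select an ROI around a seed from a 3-d t map
#'
#' All voxels with t >= threshold whose centers fall inside a cube of
#' \code{cubeEdgeMm} edge centered on the seed, retained only if they
#' belong to a face-connected supra-threshold cluster (within the cube)
#' of at least \code{minClusterMm3}.
#'
#' @param tMap3d numeric 3-d array of t values
#' @param seedMm seed coordinate, mm (length 3; voxel i spans
#'   [(i-1), i] * voxelSizeMm along each axis)
#' @param cubeEdgeMm cube edge, mm (default 15)
#' @param tThreshold inclusion threshold (default 3)
#' @param minClusterMm3 minimum cluster volume, mm^3 (default 0 = no
#'   cluster correction)
#' @param voxelSizeMm isotropic voxel size, mm (default 3)
#' @param name ROI name
#' @return a \linkS4class{RoiDefinition}; empty (with a warning) if no
#'   voxel survives
#' @export
selectRoi <- function(tMap3d, seedMm, cubeEdgeMm = 15, tThreshold = 3,
                      minClusterMm3 = 0, voxelSizeMm = 3, name = "roi") {
  dims <- dim(tMap3d)
  if (length(dims) != 3) stop("selectRoi: tMap3d must be a 3-d array")
  half <- cubeEdgeMm / 2 + 1e-9
  axOk <- lapply(1:3, function(ax)
    abs(.voxelCenters(dims[ax], voxelSizeMm) - seedMm[ax]) <= half)
  inCube <- outer(outer(axOk[[1]], axOk[[2]], "&"), axOk[[3]], "&")
  mask <- inCube & (tMap3d >= tThreshold)
  if (minClusterMm3 > 0 && any(mask)) {
    lab <- .labelClusters(mask)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes * voxelSizeMm^3 >= minClusterMm3)
    mask <- array(lab %in% keep & lab > 0L, dims)
  }
  idx <- which(mask)
  if (length(idx) == 0)
    warning("selectRoi: no voxel survives for '", name, "'; empty ROI")
  new("RoiDefinition", name = name, seedMm = as.numeric(seedMm),
      voxelIndices = as.integer(idx), tValues = as.numeric(tMap3d[idx]),
      params = list(tThreshold = tThreshold, cubeEdgeMm = cubeEdgeMm,
                    minClusterMm3 = minClusterMm3,
                    voxelSizeMm = voxelSizeMm))
}

#' Non-brain / control ROI: all positive activation inside the cube
#'
#' The threshold is dropped to t = 0 (p = 1) and every positively
#' activated voxel inside the cube is taken, with no cluster filtering —
#' the construction used for control regions where no decoding is
#' expected.
#'
#' @inheritParams selectRoi
#' @return a \linkS4class{RoiDefinition}
#' @export
makeControlRoi <- function(tMap3d, seedMm, cubeEdgeMm = 15,
                           voxelSizeMm = 3, name = "control") {
  suppressWarnings(
    selectRoi(tMap3d, seedMm, cubeEdgeMm = cubeEdgeMm,
              tThreshold = .Machine$double.eps, minClusterMm3 = 0,
              voxelSizeMm = voxelSizeMm, name = name))
}
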