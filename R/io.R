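#' Write a synthetic dataset to disk
#'
#' One 4-D NIfTI per ROI and run (voxels laid out along the first axis,
#' time along the fourth; float32), one BIDS-style tab-separated
#' events.tsv per run at the dataset root (columns: onset, duration,
#' trial_type, effector, action, error; onsets in seconds; volume
#' indexing in files is 0-based), and one JSON sidecar holding the
#' generator configuration.
#'
#' @param dataset a \linkS4class{SyntheticDataset}
#' @param directory output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeDataset <- function(dataset, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  sched <- dataset@schedule
  phase <- dataset@config$phase
  trialDur <- trialDuration(phase)
  for (r in sort(unique(sched$run_id))) {
    rows <- sched[sched$run_id == r, , drop = FALSE]
    ev <- data.frame(onset = rows$onset_s, duration = trialDur,
                     trial_type = paste(rows$effector, rows$action,
                                        sep = "_"),
                     effector = rows$effector, action = rows$action,
                     error = as.integer(rows$error))
    utils::write.table(ev,
      file.path(directory, sprintf("run-%02d_events.tsv", r)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (roi in names(dataset@runs)) {
    roiDir <- file.path(directory, paste0("roi-", roi))
    dir.create(roiDir, showWarnings = FALSE)
    for (run in dataset@runs[[roi]]) {
      arr <- array(timeseriesData(run),
                   dim = c(nrow(run@data), 1, 1, ncol(run@data)))
      img <- RNifti::asNifti(arr, pixdim = c(3, 3, 3, run@trS))
      RNifti::writeNifti(img,
        file.path(roiDir, sprintf("run-%02d_bold.nii.gz", run@runId)),
        datatype = "float")
    }
  }
  runEff <- vapply(sort(unique(sched$run_id)), function(r)
    sched$effector[sched$run_id == r][1], "")
  sidecar <- list(
    rois = names(dataset@runs),
    run_ids = sort(unique(sched$run_id)),
    run_effectors = runEff,
    tr_s = phase@trS,
    volume_indexing = "0-based",
    phase = list(preview_s = phase@previewS, plan_s = phase@planS,
                 execute_s = phase@executeS, iti_s = phase@itiS),
    lead_in_volumes = dataset@config$leadInVols,
    n_voxels = dataset@config$nVoxels,
    noise_sd = dataset@config$noiseSd,
    seed = dataset@config$seed,
    schemes = lapply(dataset@config$roiSchemes, function(s)
      list(name = s@name, pattern_amplitude = s@patternAmplitude,
           informative_fraction = s@informativeFraction)))
  jsonlite::write_json(sidecar, file.path(directory, "dataset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}

#' Read a dataset written by \code{writeDataset}
#'
#' @param directory dataset directory
#' @return a \linkS4class{SyntheticDataset} (ground truth is not
#'   persisted, so the reloaded runs carry empty ground-truth slots)
#' @export
readDataset <- function(directory) {
  sidecarPath <- file.path(directory, "dataset.json")
  if (!file.exists(sidecarPath))
    stop("readDataset: missing sidecar ", sidecarPath)
  sc <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  phase <- phaseTemplate(sc$phase$preview_s, sc$phase$plan_s,
                         sc$phase$execute_s, sc$phase$iti_s, sc$tr_s)
  runIds <- as.integer(sc$run_ids)
  sched <- vector("list", length(runIds))
  for (i in seq_along(runIds)) {
    evPath <- file.path(directory,
                        sprintf("run-%02d_events.tsv", runIds[i]))
    if (!file.exists(evPath)) stop("readDataset: missing ", evPath)
    ev <- utils::read.table(evPath, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("onset", "effector", "action", "error")
    if (!all(need %in% names(ev)))
      stop("readDataset: malformed events file ", evPath)
    sched[[i]] <- data.frame(onset_s = ev$onset, effector = ev$effector,
                             action = ev$action, run_id = runIds[i],
                             error = ev$error > 0,
                             stringsAsFactors = FALSE)
  }
  sched <- do.call(rbind, sched)
  rois <- as.character(sc$rois)
  runs <- vector("list", length(rois))
  names(runs) <- rois
  for (roi in rois) {
    runs[[roi]] <- lapply(seq_along(runIds), function(i) {
      p <- file.path(directory, paste0("roi-", roi),
                     sprintf("run-%02d_bold.nii.gz", runIds[i]))
      if (!file.exists(p)) stop("readDataset: missing image ", p)
      img <- RNifti::readNifti(p)
      d <- dim(img)
      new("RunTimeseries", data = matrix(img, d[1], d[4]), trS = sc$tr_s,
          effector = sched$effector[sched$run_id == runIds[i]][1],
          runId = runIds[i], groundTruth = list())
    })
  }
  cfgKnown <- list(phase = phase, leadInVols = as.integer(sc$lead_in_volumes),
                   nVoxels = sc$n_voxels, noiseSd = sc$noise_sd,
                   seed = sc$seed)
  new("SyntheticDataset", runs = runs, schedule = sched, config = cfgKnown)
}
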