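#' Run the full simulate -> features -> decode -> infer pipeline
#'
#' Simulates every subject of the configuration, epochs each configured
#' ROI into percent-signal-change trial tensors, runs time-resolved,
#' plan-epoch and cross-effector decoding per subject, computes group
#' statistics with FDR control, and classifies each ROI's coding
#' profile.  Per-stage seeds are derived deterministically from the
#' master seed, so a fixed configuration yields an identical report.
#'
#' @param config a \code{\link{generatorConfig}}
#' @param outDir optional output directory; when given, tidy TSV/JSON
#'   result files and accuracy-vs-time plots are written
#' @param timepoints within-trial volumes to decode (default all 17)
#' @param q FDR level
#' @param C SVM regularization parameter
#' @param highpassCycles high-pass cutoff applied before epoching
#'   (0 = off; use 5 when drift is simulated)
#' @param executeVolumes execute-phase window for profile classification
#' @return list: \code{results} (named list of
#'   \linkS4class{DecodingResult}), \code{profiles} (named list of
#'   \linkS4class{CodingProfile}), \code{accuracyTable} (tidy
#'   data.frame: subject, roi, comparison, timepoint, accuracy),
#'   \code{subjectSeeds}, \code{config}
#' @export
runPipeline <- function(config, outDir = NULL, timepoints = NULL, q = 0.05,
                        C = 1, highpassCycles = 0, executeVolumes = 10:17) {
  stopifnot(inherits(config, "generatorConfig"))
  set.seed(config$seed)
  subjectSeeds <- sample.int(.Machine$integer.max - 1, config$nSubjects)
  rois <- names(config$roiSchemes)
  accBySubject <- lapply(seq_len(config$nSubjects), function(s) {
    ds <- simulateSubject(config, subjectSeeds[s])
    out <- lapply(rois, function(roi) {
      tens <- subjectTensors(ds, roi, highpassCycles = highpassCycles,
                             phase = config$phase)
      decodeSubject(tens$hand, tens$tool, timepoints = timepoints, C = C)
    })
    names(out) <- rois
    out
  })
  results <- lapply(rois, function(roi)
    groupDecoding(lapply(accBySubject, `[[`, roi), roi = roi, q = q))
  names(results) <- rois
  profiles <- lapply(results, classifyCodingProfile,
                     executeVolumes = executeVolumes)
  accuracyTable <- do.call(rbind, lapply(seq_along(accBySubject),
    function(s) do.call(rbind, lapply(rois, function(roi) {
      a <- accBySubject[[s]][[roi]]
      data.frame(subject = s, roi = roi,
                 comparison = rep(rownames(a), ncol(a)),
                 timepoint = rep(colnames(a), each = nrow(a)),
                 accuracy = as.vector(a), stringsAsFactors = FALSE)
    }))))
  report <- list(results = results, profiles = profiles,
                 accuracyTable = accuracyTable,
                 subjectSeeds = subjectSeeds, config = unclass(config))
  if (!is.null(outDir)) writeReport(report, outDir)
  report
}

#' Write a pipeline report bundle
#'
#' Emits the tidy accuracy table and group statistics as TSV, the
#' coding-profile table as JSON and TSV, an accuracy-vs-time plot per
#' ROI with the 50\% chance line, and a provenance log (seeds and
#' configuration summary).
#'
#' @param report output of \code{\link{runPipeline}}
#' @param outDir output directory
#' @return \code{outDir}, invisibly
#' @export
writeReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$accuracyTable,
                     file.path(outDir, "accuracies.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gs <- do.call(rbind, lapply(report$results, function(r) {
    out <- groupStats(r)
    out$roi <- r@roi
    out
  }))
  utils::write.table(gs, file.path(outDir, "group_stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prof <- lapply(report$profiles, function(p)
    c(list(label = p@label), as.list(p@evidence)))
  jsonlite::write_json(prof, file.path(outDir, "profiles.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  profTab <- data.frame(roi = names(report$profiles),
                        label = vapply(report$profiles, profileLabel, ""))
  utils::write.table(profTab, file.path(outDir, "profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (roi in names(report$results)) {
    grDevices::pdf(file.path(outDir, paste0("accuracy_", roi, ".pdf")),
                   width = 7, height = 4.5)
    plotDecoding(report$results[[roi]])
    grDevices::dev.off()
  }
  prov <- list(subject_seeds = report$subjectSeeds,
               master_seed = report$config$seed,
               n_subjects = report$config$nSubjects,
               package_version =
                 as.character(utils::packageVersion("planMVPA")))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}

#' Plot time-resolved group decoding accuracies
#'
#' Mean accuracy (+/- SEM across subjects) against within-trial volume
#' for each comparison, with the 50\% chance line; FDR-significant
#' timepoints are marked.
#'
#' @param result a \linkS4class{DecodingResult}
#' @param cols line colors for the three comparisons
#' @return invisibly, the matrix of plotted means
#' @export
plotDecoding <- function(result,
                         cols = c(hand_GvsR = "firebrick",
                                  tool_GvsR = "royalblue",
                                  cross_effector = "purple")) {
  arr <- accuracies(result)
  tps <- dimnames(arr)[[3]]
  tRes <- tps[tps != "plan"]
  xs <- seq_along(tRes)
  mean2 <- apply(arr[, , tRes, drop = FALSE], c(2, 3), mean)
  sem2 <- apply(arr[, , tRes, drop = FALSE], c(2, 3), stats::sd) /
    sqrt(dim(arr)[1])
  graphics::plot(NULL, xlim = range(xs), ylim = c(0.3, 1.0),
                 xlab = "within-trial volume",
                 ylab = "decoding accuracy",
                 main = result@roi)
  graphics::abline(h = 0.5, col = "black", lwd = 1.5)
  gs <- groupStats(result)
  for (cmp in rownames(mean2)) {
    graphics::lines(xs, mean2[cmp, ], col = cols[[cmp]], lwd = 2)
    graphics::arrows(xs, mean2[cmp, ] - sem2[cmp, ],
                     xs, mean2[cmp, ] + sem2[cmp, ],
                     angle = 90, code = 3, length = 0.02,
                     col = cols[[cmp]])
    sig <- gs$fdrSignificant[gs$comparison == cmp &
                             gs$timepoint %in% tRes]
    if (any(sig))
      graphics::points(xs[sig], rep(0.33, sum(sig)), pch = 8,
                       col = cols[[cmp]])
  }
  graphics::legend("topleft", legend = rownames(mean2),
                   col = cols[rownames(mean2)], lwd = 2, bty = "n",
                   cex = 0.8)
  invisible(mean2)
}

#' Validate an on-disk dataset
#'
#' Structural diagnostics for a dataset directory: sidecar and file
#' presence, NIfTI/events volume-count consistency with the schedule,
#' effector constancy within runs, and NaN screening.  Returns
#' diagnostics rather than stopping, with one row per finding.
#'
#' @param directory dataset directory
#' @return data.frame: severity ("error"/"warning"/"ok"), check, message
#' @export
validateDataset <- function(directory) {
  notes <- list()
  note <- function(severity, check, message)
    notes[[length(notes) + 1]] <<- data.frame(
      severity = severity, check = check, message = message,
      stringsAsFactors = FALSE)
  if (!dir.exists(directory)) {
    note("error", "directory", paste("missing directory", directory))
    return(do.call(rbind, notes))
  }
  sidecarPath <- file.path(directory, "dataset.json")
  if (!file.exists(sidecarPath)) {
    note("error", "sidecar", "dataset.json is missing")
    return(do.call(rbind, notes))
  }
  sc <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  phase <- phaseTemplate(sc$phase$preview_s, sc$phase$plan_s,
                         sc$phase$execute_s, sc$phase$iti_s, sc$tr_s)
  vpt <- volumesPerTrial(phase)
  runIds <- as.integer(sc$run_ids)
  for (i in seq_along(runIds)) {
    r <- runIds[i]
    evPath <- file.path(directory, sprintf("run-%02d_events.tsv", r))
    if (!file.exists(evPath)) {
      note("error", "events", paste("missing", basename(evPath)))
      next
    }
    ev <- utils::read.table(evPath, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    if (length(unique(ev$effector)) > 1)
      note("error", "effector-constancy",
           sprintf("run %d mixes effectors; the effector must be constant within a run", r))
    expectVols <- sc$lead_in_volumes + nrow(ev) * vpt
    for (roi in as.character(sc$rois)) {
      p <- file.path(directory, paste0("roi-", roi),
                     sprintf("run-%02d_bold.nii.gz", r))
      if (!file.exists(p)) {
        note("error", "image", paste("missing", p))
        next
      }
      img <- RNifti::readNifti(p)
      nT <- dim(img)[4]
      if (nT != expectVols)
        note("error", "volume-count",
             sprintf("run %d roi %s: %d volumes, expected %d from the schedule",
                     r, roi, nT, expectVols))
      if (anyNA(img) || any(is.nan(img)))
        note("error", "nan", sprintf("run %d roi %s contains NaN", r, roi))
    }
  }
  if (length(notes) == 0)
    note("ok", "all", "dataset is structurally consistent")
  do.call(rbind, notes)
}
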