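#' Train a soft-margin linear support vector machine
#'
#' A thin wrapper around the libSVM binding in \pkg{e1071} with a linear
#' kernel and fixed regularization parameter C (default 1), no feature
#' scaling (features are expected to be rescaled to [-1, +1] already),
#' and the weight vector oriented so that a positive decision value
#' \eqn{w \cdot x + b > 0} votes for the grasp class (alphabetically
#' first class if no "grasp" label is present).
#'
#' @param x trials x voxels feature matrix, or a
#'   \linkS4class{FeatureMatrix}
#' @param labels factor/character of two class labels (ignored when
#'   \code{x} is a \code{FeatureMatrix})
#' @param C regularization parameter (default 1)
#' @return list of class \code{"linearSvm"}: \code{weights} (per voxel),
#'   \code{bias}, \code{positiveClass}, \code{negativeClass}, \code{C},
#'   \code{nTrain}
#' @export
trainLinearSvm <- function(x, labels = NULL, C = 1) {
  if (is(x, "FeatureMatrix")) {
    labels <- x@labels
    x <- x@values
  }
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("trainLinearSvm: exactly two classes are required")
  fit <- e1071::svm(x, labels, kernel = "linear", cost = C, scale = FALSE,
                    type = "C-classification")
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libSVM orders the decision sign by first appearance in the training
  # data, not by factor level; the decision.values column name states the
  # authoritative "positive/negative" class pair
  dv <- attr(stats::predict(fit, x[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  pair <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  pos <- pair[1]
  neg <- pair[2]
  want <- if ("grasp" %in% fit$levels) "grasp" else sort(fit$levels)[1]
  if (pos != want) {
    w <- -w; b <- -b
    tmp <- pos; pos <- neg; neg <- tmp
  }
  structure(list(weights = w, bias = b, positiveClass = pos,
                 negativeClass = neg, C = C, nTrain = nrow(x)),
            class = "linearSvm")
}

#' @export
print.linearSvm <- function(x, ...) {
  cat(sprintf("linearSvm: %d voxels, C = %g, %d training trials (+: %s)\n",
              length(x$weights), x$C, x$nTrain, x$positiveClass))
  invisible(x)
}

#' Predict with a linear SVM
#'
#' Decision value \eqn{w \cdot x + b}; an exact tie (decision value 0) is
#' assigned to the lexicographically first class label, keeping
#' prediction deterministic.
#'
#' @param model a \code{"linearSvm"}
#' @param x trials x voxels matrix
#' @return list: \code{labels} (character), \code{decision} (numeric)
#' @export
predictLinearSvm <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  dec <- drop(x %*% model$weights) + model$bias
  first <- sort(c(model$positiveClass, model$negativeClass))[1]
  lab <- ifelse(dec > 0, model$positiveClass,
         ifelse(dec < 0, model$negativeClass, first))
  list(labels = lab, decision = dec)
}

# per-voxel [-1,+1] scaling parameters estimated on training rows and
# applied to arbitrary rows (leakage-safe rescaling variant)
.foldScaler <- function(train) {
  lo <- apply(train, 2, min)
  hi <- apply(train, 2, max)
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1
  function(m) {
    out <- sweep(sweep(m, 2, (lo + hi) / 2), 2, rng / 2, "/")
    out[, const] <- 0
    out
  }
}

#' Leave-one-trial-pair-out cross-validated accuracy
#'
#' Trials of each class are paired by within-class chronological rank
#' (first grasp with first reach, and so on); each fold reserves one
#' pair — one trial from each class — for testing and trains on all
#' remaining trials.  With N pairs (N = smaller class count) there are N
#' folds and 2N test predictions; surplus trials of the larger class
#' always stay in training and are never tested.  Accuracy = correct
#' test predictions / 2N.
#'
#' @param x trials x voxels matrix (rows in chronological order), or a
#'   \linkS4class{FeatureMatrix}
#' @param labels two-class labels (ignored for a \code{FeatureMatrix})
#' @param C SVM regularization parameter
#' @param rescaleWithinTrainFold if TRUE, per-voxel [-1, +1] scaling is
#'   fit on each fold's training trials and applied to its test trials
#'   (leakage-safe variant); if FALSE (default, replicating the
#'   all-trials convention) \code{x} is used as given
#' @return list: \code{accuracy}, \code{folds} (data.frame: fold,
#'   testIndex, trueLabel, predicted, correct)
#' @export
leaveOnePairOut <- function(x, labels = NULL, C = 1,
                            rescaleWithinTrainFold = FALSE) {
  if (is(x, "FeatureMatrix")) {
    labels <- x@labels
    x <- x@values
  }
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2)
    stop("leaveOnePairOut: exactly two classes are required")
  idxA <- which(labels == classes[1])
  idxB <- which(labels == classes[2])
  if (length(idxA) < 3 || length(idxB) < 3)
    stop("leaveOnePairOut: at least 3 trials per class are required")
  nPairs <- min(length(idxA), length(idxB))
  folds <- vector("list", nPairs)
  for (k in seq_len(nPairs)) {
    test <- c(idxA[k], idxB[k])
    train <- setdiff(seq_along(labels), test)
    xt <- x[train, , drop = FALSE]
    xs <- x[test, , drop = FALSE]
    if (rescaleWithinTrainFold) {
      sc <- .foldScaler(xt)
      xt <- sc(xt)
      xs <- sc(xs)
    }
    model <- trainLinearSvm(xt, labels[train], C = C)
    pred <- predictLinearSvm(model, xs)$labels
    folds[[k]] <- data.frame(fold = k, testIndex = test,
                             trueLabel = labels[test], predicted = pred,
                             correct = pred == labels[test],
                             stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, folds)
  list(accuracy = mean(folds$correct), folds = folds)
}

#' Bidirectional cross-effector (cross-condition) decoding accuracy
#'
#' One classifier is trained on all trials of one effector and tested on
#' all trials of the other (a single train-and-test iteration per
#' direction, using all available data); the reported accuracy is the
#' mean of the two directions, with both directions retained for
#' asymmetry checks.
#'
#' @param xHand,labelsHand hand-run features and labels (or a
#'   \linkS4class{FeatureMatrix} as \code{xHand})
#' @param xTool,labelsTool tool-run features and labels
#' @param C SVM regularization parameter
#' @return list: \code{accuracy} (mean of directions),
#'   \code{handToTool}, \code{toolToHand}
#' @export
crossEffectorAccuracy <- function(xHand, labelsHand = NULL, xTool,
                                  labelsTool = NULL, C = 1) {
  if (is(xHand, "FeatureMatrix")) {
    labelsHand <- xHand@labels
    xHand <- xHand@values
  }
  if (is(xTool, "FeatureMatrix")) {
    labelsTool <- xTool@labels
    xTool <- xTool@values
  }
  labelsHand <- as.character(labelsHand)
  labelsTool <- as.character(labelsTool)
  if (length(unique(labelsHand)) != 2 || length(unique(labelsTool)) != 2)
    stop("crossEffectorAccuracy: both classes must be present for both effectors")
  mH <- trainLinearSvm(xHand, labelsHand, C = C)
  accHT <- mean(predictLinearSvm(mH, xTool)$labels == labelsTool)
  mT <- trainLinearSvm(xTool, labelsTool, C = C)
  accTH <- mean(predictLinearSvm(mT, xHand)$labels == labelsHand)
  list(accuracy = (accHT + accTH) / 2, handToTool = accHT,
       toolToHand = accTH)
}

#' Voxel weights from a single-shot fit on all trials
#'
#' Trains one linear SVM on all trials of a pairwise comparison and
#' returns its signed per-voxel weights, oriented so a voxel responding
#' more strongly to grasp gets a positive weight.
#'
#' @inheritParams trainLinearSvm
#' @return numeric weight vector, one per voxel
#' @export
extractVoxelWeights <- function(x, labels = NULL, C = 1) {
  model <- trainLinearSvm(x, labels, C = C)
  w <- model$weights
  if (model$positiveClass != "grasp" &&
      "grasp" %in% c(model$positiveClass, model$negativeClass))
    w <- -w
  w
}

#' Top-k voxel weight fingerprint
#'
#' Orders voxels by their maximum absolute weight across the pairwise
#' comparisons, selects the top k (ties broken by lowest voxel index),
#' and within each comparison normalizes the selected weights' magnitudes
#' to a maximum of 1, preserving signs.  The same voxel set is used for
#' every comparison.
#'
#' @param weightMaps voxels x comparisons matrix of signed weights (a
#'   single weight vector is treated as one comparison)
#' @param k number of voxels to keep (default 10)
#' @return list: \code{voxels} (indices, ordered by discriminativeness),
#'   \code{weights} (k x comparisons, max magnitude 1 per comparison)
#' @export
weightFingerprint <- function(weightMaps, k = 10) {
  if (is.vector(weightMaps)) weightMaps <- matrix(weightMaps, ncol = 1)
  if (k > nrow(weightMaps))
    stop("weightFingerprint: k exceeds the voxel count")
  score <- apply(abs(weightMaps), 1, max)
  sel <- order(-score, seq_along(score))[seq_len(k)]
  w <- weightMaps[sel, , drop = FALSE]
  maxAbs <- apply(abs(w), 2, max)
  maxAbs[maxAbs == 0] <- 1
  w <- sweep(w, 2, maxAbs, "/")
  list(voxels = sel, weights = w)
}

#' Time-resolved and plan-epoch decoding for one subject
#'
#' For every within-trial volume and for the plan epoch, computes the
#' within-hand and within-tool grasp-vs-reach leave-one-pair-out
#' accuracies and the bidirectional cross-effector accuracy.  Features at
#' each timepoint are rescaled to [-1, +1] per voxel across all trials of
#' the pairwise comparison (each effector's trials separately), unless
#' the leakage-safe within-fold variant is requested.
#'
#' @param tensorHand,tensorTool epoched \linkS4class{TrialTensor}s for
#'   the hand and tool runs of one subject
#' @param timepoints within-trial volumes to decode (default all)
#' @param planEpoch include the plan-epoch column (default TRUE)
#' @param planVolumes volumes averaged for the plan epoch
#' @param C SVM regularization parameter
#' @param rescaleWithinTrainFold leakage-safe rescaling for the
#'   within-effector cross-validation (see \code{\link{leaveOnePairOut}})
#' @return accuracy matrix: 3 comparisons (\code{hand_GvsR},
#'   \code{tool_GvsR}, \code{cross_effector}) x timepoints (+
#'   \code{"plan"})
#' @export
decodeSubject <- function(tensorHand, tensorTool, timepoints = NULL,
                          planEpoch = TRUE, planVolumes = 8:9, C = 1,
                          rescaleWithinTrainFold = FALSE) {
  nv <- dim(tensorHand@values)[2] - 1L
  if (is.null(timepoints)) timepoints <- seq_len(nv)
  cols <- c(if (length(timepoints) > 0) paste0("t", timepoints),
            if (planEpoch) "plan")
  if (length(cols) == 0)
    stop("decodeSubject: nothing to decode")
  acc <- matrix(NA_real_, 3, length(cols),
                dimnames = list(.comparisons, cols))
  featAt <- function(tensor, tp) {
    fm <- if (identical(tp, "plan")) planEpochAverage(tensor, planVolumes)
          else timepointFeatures(tensor, tp)
    if (rescaleWithinTrainFold) fm else rescaleFeatures(fm)
  }
  for (j in seq_along(cols)) {
    tp <- if (cols[j] == "plan") "plan" else timepoints[j]
    fh <- featAt(tensorHand, tp)
    ft <- featAt(tensorTool, tp)
    acc["hand_GvsR", j] <-
      leaveOnePairOut(fh, C = C,
                      rescaleWithinTrainFold = rescaleWithinTrainFold)$accuracy
    acc["tool_GvsR", j] <-
      leaveOnePairOut(ft, C = C,
                      rescaleWithinTrainFold = rescaleWithinTrainFold)$accuracy
    if (rescaleWithinTrainFold) {
      fh <- rescaleFeatures(fh)
      ft <- rescaleFeatures(ft)
    }
    acc["cross_effector", j] <- crossEffectorAccuracy(fh, xTool = ft,
                                                      C = C)$accuracy
  }
  acc
}

#' Epoch one subject's dataset into hand and tool trial tensors
#'
#' Convenience wrapper: concatenates the epoched trials of all runs of
#' each effector for one ROI of a \linkS4class{SyntheticDataset},
#' optionally high-pass filtering each run first.
#'
#' @param dataset a \linkS4class{SyntheticDataset}
#' @param roi ROI name (default: first configured ROI)
#' @param highpassCycles high-pass cutoff in cycles/run applied before
#'   epoching (0 = no filtering)
#' @param phase a \linkS4class{PhaseTemplate}
#' @return list: \code{hand}, \code{tool} (each a
#'   \linkS4class{TrialTensor})
#' @export
subjectTensors <- function(dataset, roi = NULL, highpassCycles = 0,
                           phase = phaseTemplate()) {
  if (is.null(roi)) roi <- names(dataset@runs)[1]
  runs <- dataset@runs[[roi]]
  sched <- dataset@schedule
  tensors <- lapply(runs, function(r) {
    if (highpassCycles > 0) r <- highpassFilter(r, highpassCycles)
    epochTrials(r, sched, phase = phase)
  })
  eff <- vapply(runs, effector, "")
  list(hand = bindTensors(tensors[eff == "hand"]),
       tool = bindTensors(tensors[eff == "tool"]))
}
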