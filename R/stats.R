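#' One-sample two-tailed t test of accuracies against chance
#'
#' \eqn{t = (\bar a - 0.5) / (s / \sqrt{n})} with n - 1 degrees of
#' freedom.  Degenerate zero-variance input follows a declared
#' convention: mean exactly at chance gives t = 0, p = 1; mean off
#' chance with zero variance is treated as maximally significant
#' (t = +/- Inf, p set to the smallest positive double).
#'
#' @param accuracies per-subject accuracies (>= 2 subjects)
#' @param chance chance level (default 0.5)
#' @return list: \code{t}, \code{p}, \code{dof}, \code{mean}
#' @export
groupTtestVsChance <- function(accuracies, chance = 0.5) {
  n <- length(accuracies)
  if (n < 2) stop("groupTtestVsChance: at least 2 subjects are required")
  m <- mean(accuracies)
  s <- stats::sd(accuracies)
  if (s == 0) {
    if (m == chance) return(list(t = 0, p = 1, dof = n - 1, mean = m))
    return(list(t = sign(m - chance) * Inf, p = .Machine$double.xmin,
                dof = n - 1, mean = m))
  }
  tval <- (m - chance) / (s / sqrt(n))
  list(t = tval, p = 2 * stats::pt(-abs(tval), n - 1), dof = n - 1,
       mean = m)
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up FDR control at level q over one declared family of p values.
#'
#' @param pValues numeric vector of p values in (0, 1]
#' @param q FDR level (default 0.05)
#' @return logical mask, TRUE where the test survives
#' @export
fdrMask <- function(pValues, q = 0.05) {
  if (length(pValues) == 0) stop("fdrMask: empty p-value family")
  stats::p.adjust(pValues, method = "BH") <= q
}

#' Group-level permutation p value for plan-epoch decoding
#'
#' Two-level randomization test: for each permutation, every subject's
#' class labels are permuted (preserving class counts), the decoding
#' analysis is re-run per subject, and the across-subject mean accuracy
#' forms one draw from the group null.  The p value uses the add-one
#' estimator \eqn{p = (1 + \#\{null \ge observed\}) / (1 + n_{perm})}, so
#' reaching p < 0.001 requires at least 999 permutations.
#'
#' @param featureList list of per-subject trials x voxels matrices
#'   (rescaled features)
#' @param labelList list of per-subject label vectors
#' @param observedAccuracy the observed across-subject mean accuracy
#' @param nPerm number of permutations (>= 99)
#' @param seed RNG seed
#' @param C SVM regularization parameter
#' @return list: \code{p}, \code{null} (the permuted group means)
#' @export
permutationPvalue <- function(featureList, labelList, observedAccuracy,
                              nPerm = 1000, seed = 1, C = 1) {
  if (nPerm < 99) stop("permutationPvalue: nPerm must be at least 99")
  set.seed(seed)
  null <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    accs <- vapply(seq_along(featureList), function(s) {
      labs <- sample(labelList[[s]])
      leaveOnePairOut(featureList[[s]], labs, C = C)$accuracy
    }, 0)
    null[b] <- mean(accs)
  }
  list(p = (1 + sum(null >= observedAccuracy)) / (1 + nPerm), null = null)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Standard within-subject F with sphericity correction: the
#' Greenhouse-Geisser epsilon is computed from the double-centered
#' sample covariance \eqn{\tilde S} of the repeated measures,
#' \eqn{\epsilon = \mathrm{tr}(\tilde S)^2 / ((k-1)\,
#' \mathrm{tr}(\tilde S^2))}, bounded in [1/(k-1), 1], and both degrees
#' of freedom are multiplied by it before computing p.
#'
#' @param accuracyMatrix subjects x conditions numeric matrix (no
#'   missing cells)
#' @return list: \code{F}, \code{epsilon}, \code{dofNum}, \code{dofDen}
#'   (GG-adjusted, fractional), \code{p}
#' @export
rmAnovaGG <- function(accuracyMatrix) {
  m <- as.matrix(accuracyMatrix)
  if (anyNA(m)) stop("rmAnovaGG: missing cells are not allowed")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3 || k < 2)
    stop("rmAnovaGG: at least 3 subjects and 2 conditions are required")
  grand <- mean(m)
  condMeans <- colMeans(m)
  subjMeans <- rowMeans(m)
  ssCond <- n * sum((condMeans - grand)^2)
  ssErr <- sum((m - outer(subjMeans, condMeans, "+") + grand)^2)
  dfCond <- k - 1
  dfErr <- (k - 1) * (n - 1)
  if (ssErr == 0 && ssCond == 0)
    return(list(F = 0, epsilon = 1, dofNum = dfCond, dofDen = dfErr, p = 1))
  Fval <- (ssCond / dfCond) / (ssErr / dfErr)
  S <- stats::cov(m)
  Sdc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  denom <- (k - 1) * sum(Sdc^2)
  eps <- if (denom == 0) 1 else sum(diag(Sdc))^2 / denom
  eps <- min(1, max(1 / (k - 1), eps))
  p <- stats::pf(Fval, dfCond * eps, dfErr * eps, lower.tail = FALSE)
  list(F = Fval, epsilon = eps, dofNum = dfCond * eps,
       dofDen = dfErr * eps, p = p)
}

#' FDR-corrected pairwise paired follow-up t tests
#'
#' All k(k-1)/2 pairwise paired t tests among the repeated measures,
#' two-tailed, with Benjamini-Hochberg correction across the pairs.
#'
#' @param accuracyMatrix subjects x conditions matrix with column names
#' @param q FDR level for the follow-up family
#' @return data.frame: conditionA, conditionB, t, dof, p, fdrSignificant
#' @export
pairedFollowups <- function(accuracyMatrix, q = 0.05) {
  m <- as.matrix(accuracyMatrix)
  k <- ncol(m)
  if (k < 2) stop("pairedFollowups: at least 2 conditions are required")
  nms <- colnames(m)
  if (is.null(nms)) nms <- paste0("c", seq_len(k))
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(pr) {
    d <- m[, pr[1]] - m[, pr[2]]
    tt <- groupTtestVsChance(d + 0.5)   # paired t == one-sample t on diffs
    c(t = tt$t, dof = tt$dof, p = tt$p)
  })
  out <- data.frame(conditionA = nms[pairs[1, ]],
                    conditionB = nms[pairs[2, ]],
                    t = res["t", ], dof = res["dof", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$fdrSignificant <- fdrMask(out$p, q)
  out
}

#' Assemble a group DecodingResult with t tests and FDR flags
#'
#' Stacks per-subject accuracy matrices (from
#' \code{\link{decodeSubject}}), tests every comparison x timepoint cell
#' against 50\% chance with a two-tailed one-sample t test, and applies
#' Benjamini-Hochberg FDR over the declared per-ROI family: all t tests
#' performed within the ROI (every decoded timepoint and the plan epoch,
#' across the three comparisons) form one family.  Families are never
#' pooled across ROIs.
#'
#' @param accList list of per-subject comparison x timepoint accuracy
#'   matrices
#' @param roi ROI name
#' @param q FDR level (default 0.05)
#' @param chance chance accuracy (default 0.5)
#' @return a \linkS4class{DecodingResult}
#' @export
groupDecoding <- function(accList, roi = "roi", q = 0.05, chance = 0.5) {
  stopifnot(length(accList) >= 2)
  d <- dim(accList[[1]])
  arr <- array(NA_real_, c(length(accList), d[1], d[2]),
               dimnames = c(list(NULL), dimnames(accList[[1]])))
  for (s in seq_along(accList)) arr[s, , ] <- accList[[s]]
  cells <- expand.grid(comparison = rownames(accList[[1]]),
                       timepoint = colnames(accList[[1]]),
                       stringsAsFactors = FALSE)
  stats <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    a <- arr[, cells$comparison[i], cells$timepoint[i]]
    tt <- groupTtestVsChance(a, chance)
    data.frame(comparison = cells$comparison[i],
               timepoint = cells$timepoint[i], meanAccuracy = tt$mean,
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  }))
  stats$fdrSignificant <- fdrMask(stats$p, q)
  new("DecodingResult", roi = roi, accuracies = arr, groupStats = stats)
}

#' Coding-profile label from evidence booleans
#'
#' The hard decision table mapping plan-epoch significance of the three
#' pairwise comparisons, plus execute-phase significance, to the
#' categorical per-region profile:
#' hand only -> \code{hand_specific}; tool only -> \code{tool_specific};
#' hand and tool without cross-effector transfer ->
#' \code{effector_specific_both}; all three -> \code{effector_independent};
#' neither during planning but significant after movement onset ->
#' \code{execute_only}; otherwise \code{null}.
#'
#' @param handSig,toolSig,crossSig plan-epoch FDR significance of the
#'   within-hand, within-tool and cross-effector comparisons
#' @param executeSig any FDR-significant within-effector decoding at the
#'   execute-phase volumes
#' @return a profile label string
#' @export
profileFromEvidence <- function(handSig, toolSig, crossSig, executeSig) {
  if (handSig && !toolSig) return("hand_specific")
  if (toolSig && !handSig) return("tool_specific")
  if (handSig && toolSig && !crossSig) return("effector_specific_both")
  if (handSig && toolSig && crossSig) return("effector_independent")
  if (!handSig && !toolSig && executeSig) return("execute_only")
  "null"
}

#' Classify the coding profile of an ROI from its decoding result
#'
#' Derives the evidence booleans from a \linkS4class{DecodingResult}:
#' plan-epoch FDR flags for the three comparisons, and execute-phase
#' significance as any FDR-flagged within-effector cell among the
#' time-resolved volumes from movement onset onward.
#'
#' @param result a \linkS4class{DecodingResult} holding both the
#'   time-resolved and the plan-epoch cells
#' @param executeVolumes within-trial volumes counted as the
#'   execute-phase window (default 10:17 under the default template:
#'   movement onset through the ITI, covering the hemodynamic lag)
#' @return a \linkS4class{CodingProfile}
#' @export
classifyCodingProfile <- function(result, executeVolumes = 10:17) {
  gs <- result@groupStats
  planFlag <- function(cmp) {
    row <- gs[gs$timepoint == "plan" & gs$comparison == cmp, ]
    if (nrow(row) != 1)
      stop("classifyCodingProfile: missing plan-epoch comparison '", cmp, "'")
    row$fdrSignificant
  }
  ev <- c(handSig = planFlag("hand_GvsR"),
          toolSig = planFlag("tool_GvsR"),
          crossSig = planFlag("cross_effector"))
  execCells <- gs[gs$timepoint %in% paste0("t", executeVolumes) &
                  gs$comparison %in% c("hand_GvsR", "tool_GvsR"), ]
  ev["executeSig"] <- any(execCells$fdrSignificant)
  new("CodingProfile", roi = result@roi,
      label = profileFromEvidence(ev["handSig"], ev["toolSig"],
                                  ev["crossSig"], ev["executeSig"]),
      evidence = ev)
}
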