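#' Build a counterbalanced trial schedule
#'
#' Emits one row per trial across all runs of a session.  Within each run
#' every condition appears exactly \code{trialsPerCondition} times, trials
#' abut at the fixed trial duration, and the effector is constant within a
#' run (runs alternate effectors).  When \code{counterbalance} is TRUE the
#' condition orders are drawn so that, pooled across all runs of one
#' effector, each ordered first-order transition (grasp->grasp,
#' grasp->reach, reach->grasp, reach->reach) occurs equally often to
#' within one count — i.e., each trial type is preceded and followed
#' equally often by every other trial type.
#'
#' The sequences are built by randomized construction with local swap
#' repair and rejection-resampling restarts, until the pooled transition
#' matrix is uniform within +/-1.
#'
#' @param nRunsPerEffector runs per effector (default 4)
#' @param trialsPerCondition repetitions of each condition per run
#'   (default 10; must be >= 2 when counterbalancing)
#' @param phase a \linkS4class{PhaseTemplate}
#' @param seed integer RNG seed; fixed seed gives an identical schedule
#' @param effectors character vector of effectors; runs alternate through
#'   it (default \code{c("hand", "tool")})
#' @param conditions condition labels (default \code{c("grasp", "reach")})
#' @param counterbalance enforce the pooled transition-balance property
#' @param leadInVols baseline volumes before the first trial onset of each
#'   run, so the first trial's "volume -1" baseline exists
#' @param errorRate probability that a trial is flagged as a performance
#'   error (excluded from decoding downstream)
#' @return data.frame with columns \code{onset_s}, \code{effector},
#'   \code{action}, \code{run_id}, \code{error}
#' @examples
#' sch <- makeTrialSchedule(1, 10, seed = 7, effectors = "hand")
#' table(sch$action)  # 10 grasp, 10 reach
#' @export
makeTrialSchedule <- function(nRunsPerEffector = 4, trialsPerCondition = 10,
                              phase = phaseTemplate(), seed = 1,
                              effectors = c("hand", "tool"),
                              conditions = c("grasp", "reach"),
                              counterbalance = TRUE, leadInVols = 2L,
                              errorRate = 0) {
  if (nRunsPerEffector < 1 || trialsPerCondition < 1)
    stop("makeTrialSchedule: counts must be positive")
  if (counterbalance && length(conditions) > 1 && trialsPerCondition < 2)
    stop("makeTrialSchedule: transition counterbalancing is infeasible with ",
         "fewer than 2 trials per condition; lower the demand or add trials")
  set.seed(seed)
  seqsByEff <- lapply(effectors, function(e)
    .balancedSequences(nRunsPerEffector, trialsPerCondition, conditions,
                       counterbalance))
  names(seqsByEff) <- effectors

  trialDur <- trialDuration(phase)
  nRuns <- nRunsPerEffector * length(effectors)
  runEff <- rep(effectors, length.out = nRuns)  # alternate effectors
  effCounter <- stats::setNames(rep(0L, length(effectors)), effectors)
  out <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    e <- runEff[r]
    effCounter[e] <- effCounter[e] + 1L
    s <- seqsByEff[[e]][[effCounter[e]]]
    onset0 <- leadInVols * phase@trS
    out[[r]] <- data.frame(
      onset_s = onset0 + (seq_along(s) - 1) * trialDur,
      effector = e, action = s, run_id = r,
      error = stats::runif(length(s)) < errorRate,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Randomized sequence construction with local swap repair: draw one
# balanced random order per run, then repeatedly swap two unlike trials
# within a run whenever the swap does not worsen the pooled transition
# imbalance, until the pooled counts are uniform within +/-1 (with
# rejection-resampling restarts).  Small designs converge in milliseconds.
.balancedSequences <- function(nRuns, reps, conditions, counterbalance,
                               maxRestarts = 50L, maxSwaps = 5000L) {
  nc <- length(conditions)
  if (nc == 1 || !counterbalance) {
    return(lapply(seq_len(nRuns), function(r)
      sample(rep(conditions, reps))))
  }
  poolCounts <- function(seqs) {
    counts <- matrix(0L, nc, nc, dimnames = list(conditions, conditions))
    for (s in seqs)
      for (i in 2:length(s))
        counts[s[i - 1], s[i]] <- counts[s[i - 1], s[i]] + 1L
    counts
  }
  dev <- function(counts) sum((counts - mean(counts))^2)
  for (attempt in seq_len(maxRestarts)) {
    seqs <- lapply(seq_len(nRuns), function(r) sample(rep(conditions, reps)))
    counts <- poolCounts(seqs)
    for (iter in seq_len(maxSwaps)) {
      if (max(counts) - min(counts) <= 1L) return(seqs)
      r <- sample.int(nRuns, 1)
      s <- seqs[[r]]
      i <- sample.int(length(s), 1)
      other <- which(s != s[i])
      if (length(other) == 0) break
      j <- other[sample.int(length(other), 1)]
      s2 <- s
      s2[c(i, j)] <- s2[c(j, i)]
      seqs2 <- seqs
      seqs2[[r]] <- s2
      counts2 <- poolCounts(seqs2)
      if (dev(counts2) <= dev(counts)) {
        seqs <- seqs2
        counts <- counts2
      }
    }
  }
  stop("makeTrialSchedule: could not counterbalance transitions for this ",
       "design; relax the balance demand or change the trial counts")
}

#' Pooled first-order transition counts of a schedule
#'
#' Counts ordered condition transitions within runs, pooled across all
#' runs of one effector.  Used to verify the counterbalancing property.
#'
#' @param schedule a schedule data.frame (see
#'   \code{\link{makeTrialSchedule}})
#' @param effectorName which effector's runs to pool
#' @return square integer matrix of transition counts
#' @export
transitionCounts <- function(schedule, effectorName) {
  sch <- schedule[schedule$effector == effectorName, , drop = FALSE]
  conds <- sort(unique(sch$action))
  counts <- matrix(0L, length(conds), length(conds),
                   dimnames = list(conds, conds))
  for (r in unique(sch$run_id)) {
    s <- sch$action[sch$run_id == r]
    if (length(s) < 2) next
    for (i in 2:length(s))
      counts[s[i - 1], s[i]] <- counts[s[i - 1], s[i]] + 1L
  }
  counts
}
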