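test_that("default design yields 8 runs of 20 trials and 342 volumes", {
  cfg <- generatorConfig(nVoxels = 4, trialsPerCondition = 10,
                         roiSchemes = list(spoc = codingScheme("null")))
  ds <- simulateSubject(cfg, 1)
  runs <- datasetRuns(ds, "spoc")
  expect_length(runs, 8)
  expect_equal(sum(vapply(runs, effector, "") == "hand"), 4)
  sch <- datasetSchedule(ds)
  expect_equal(nrow(sch), 160)
  for (r in runs) {
    # 20 trials x 17 volumes/trial plus the 2-volume baseline lead-in
    expect_equal(ncol(timeseriesData(r)), 2 + 20 * 17)
    expect_false(anyNA(timeseriesData(r)))
  }
  # default parieto-frontal ROI size is 54 voxels
  expect_equal(generatorConfig()$nVoxels, 54)
})

test_that("fixed seeds give float-identical data; different seeds differ", {
  cfg <- tinyConfig(nVoxels = 6, reps = 3, schemeName = "effector_independent",
                    amplitude = 0.5)
  a <- simulateSubject(cfg, 9)
  b <- simulateSubject(cfg, 9)
  expect_identical(lapply(datasetRuns(a, "roi"), timeseriesData),
                   lapply(datasetRuns(b, "roi"), timeseriesData))
  d <- simulateSubject(cfg, 10)
  expect_false(identical(timeseriesData(datasetRuns(a, "roi")[[1]]),
                         timeseriesData(datasetRuns(d, "roi")[[1]])))
})

test_that("amplitude-zero schemes leave condition means equal up to noise", {
  # two-sample test on evoked plan-epoch means over repeated simulations:
  # the rejection rate must stay near the nominal level
  set.seed(11)
  pvals <- replicate(200, {
    cfg <- tinyConfig(schemeName = "effector_independent", amplitude = 0,
                      nVoxels = 4, reps = 5, seed = sample.int(1e8, 1))
    ds <- simulateSubject(cfg, sample.int(1e8, 1))
    fm <- planEpochAverage(subjectTensors(ds, "roi")$hand)
    x <- rowMeans(featureValues(fm))
    t.test(x[featureLabels(fm) == "grasp"],
           x[featureLabels(fm) == "reach"])$p.value
  })
  expect_gt(mean(pvals < 0.05), 0.005)
  expect_lt(mean(pvals < 0.05), 0.12)
})

test_that("schemes plant differences only where they declare them", {
  # noiseless construction checks on every scheme
  planVols <- 4:9
  execVols <- 10
  checkDiff <- function(schemeName, eff, vols, expectZero) {
    cfg <- tinyConfig(schemeName = schemeName, amplitude = 1,
                      nVoxels = 6, reps = 3, noiseSd = 0)
    ds <- simulateSubject(cfg, 6)
    tens <- subjectTensors(ds, "roi")[[eff]]
    for (v in vols) {
      d <- conditionDiff(timepointFeatures(tens, v))
      if (expectZero) expect_equal(max(abs(d)), 0)
      else expect_gt(max(abs(d)), 0.1)
    }
  }
  # hand_specific: nonzero on hand runs during plan, exactly 0 on tool runs
  checkDiff("hand_specific", "hand", c(6, 9), FALSE)
  checkDiff("hand_specific", "tool", 1:17, TRUE)
  checkDiff("tool_specific", "tool", c(6, 9), FALSE)
  checkDiff("tool_specific", "hand", 1:17, TRUE)
  # any scheme: preview volumes are uninformative
  for (s in c("hand_specific", "effector_specific_both",
              "effector_independent"))
    checkDiff(s, "hand", 1:3, TRUE)
  # execute_only: zero through the whole plan period
  checkDiff("execute_only", "hand", 1:9, TRUE)
  checkDiff("execute_only", "hand", 11:12, FALSE)
  # cue_transient: confined to the early plan response
  checkDiff("cue_transient", "hand", c(1:4, 12:17), TRUE)
  checkDiff("cue_transient", "hand", 5:7, FALSE)
  # null: nothing anywhere
  checkDiff("null", "hand", 1:17, TRUE)
})

test_that("shared-code schemes reuse one pattern across effectors", {
  cfg <- tinyConfig(schemeName = "effector_independent", amplitude = 1,
                    nVoxels = 6, reps = 3, noiseSd = 0)
  ds <- simulateSubject(cfg, 7)
  tens <- subjectTensors(ds, "roi")
  dh <- conditionDiff(planEpochAverage(tens$hand))
  dt <- conditionDiff(planEpochAverage(tens$tool))
  expect_equal(dh, dt, tolerance = 1e-10)
  # effector_specific_both draws independent patterns instead
  cfg2 <- tinyConfig(schemeName = "effector_specific_both", amplitude = 1,
                     nVoxels = 20, reps = 3, noiseSd = 0)
  ds2 <- simulateSubject(cfg2, 7)
  tens2 <- subjectTensors(ds2, "roi")
  dh2 <- conditionDiff(planEpochAverage(tens2$hand))
  dt2 <- conditionDiff(planEpochAverage(tens2$tool))
  expect_false(isTRUE(all.equal(dh2, dt2, tolerance = 1e-3)))
})

test_that("generator configuration is validated", {
  expect_error(generatorConfig(noiseSd = -1), "non-negative")
  expect_error(generatorConfig(nSubjects = 0), "positive")
  expect_error(generatorConfig(ar1Rho = 1), "< 1")
  expect_error(codingScheme("banana"), "unknown scheme")
  expect_error(codingScheme("null", patternAmplitude = -2),
               "non-negative")
  sch <- makeTrialSchedule(1, 2, seed = 1, effectors = "hand")
  expect_error(simulateRoiTimeseries(codingScheme("null"), sch,
                                     noiseSd = -0.5), "non-negative")
})

test_that("AR(1) noise and cosine drift are injected as configured", {
  cfg <- tinyConfig(nVoxels = 40, reps = 10, noiseSd = 1,
                    ar1Rho = 0.6)
  ds <- simulateSubject(cfg, 12)
  y <- timeseriesData(datasetRuns(ds, "roi")[[1]])
  # lag-1 autocorrelation of voxel residuals around the mean time course
  resid <- sweep(y, 2, colMeans(y))
  r1 <- mean(apply(resid, 1, function(v)
    cor(v[-1], v[-length(v)])))
  expect_gt(r1, 0.35)
  cfgD <- tinyConfig(nVoxels = 4, reps = 10, noiseSd = 0,
                     driftAmplitude = 2, driftCycles = 2)
  dsD <- simulateSubject(cfgD, 12)
  runD <- datasetRuns(dsD, "roi")[[1]]
  # drift inflates low-frequency power; the high-pass stage removes it
  filt <- highpassFilter(runD, 5)
  sdBefore <- sd(timeseriesData(runD)[1, ])
  sdAfter <- sd(timeseriesData(filt)[1, ])
  expect_lt(sdAfter, sdBefore)
})

test_that("block localizer plants category-selective responses", {
  sim <- simulateBlockLocalizer(noiseSd = 0, seed = 2)
  expect_equal(unique(sim$blocks$duration_s), 16)
  # block duration in volumes = 8 at TR 2 s
  expect_equal(unique(sim$blocks$duration_s) / 2, 8)
  y <- timeseriesData(sim$run)
  pref <- sim$run@groundTruth$preferred
  # noiseless: a tool-selective voxel responds more in tools blocks than
  # in each other block type
  toolVox <- which(pref == "tools")[1]
  blockMean <- function(cat) {
    rows <- sim$blocks[sim$blocks$category == cat, ]
    mean(unlist(lapply(seq_len(nrow(rows)), function(b) {
      v0 <- as.integer(rows$onset_s[b] / 2)
      y[toolVox, (v0 + 3):(v0 + 8)]   # steady-state block volumes
    })))
  }
  for (other in c("bodies", "objects", "scrambled"))
    expect_gt(blockMean("tools"), blockMean(other))
  expect_error(simulateBlockLocalizer(categories = "tools"),
               "at least 2")
})

test_that("zero selectivity leaves no voxel surviving the conjunction at t=3", {
  # Monte-Carlo over simulated localizer runs: with selectivity 0 the
  # expected conjunction-surviving voxel count is ~0
  set.seed(13)
  survivors <- replicate(100, {
    sim <- simulateBlockLocalizer(selectivityAmplitude = 0,
                                  nVoxPerCategory = 5, noiseSd = 1,
                                  seed = sample.int(1e8, 1))
    y <- timeseriesData(sim$run)
    nVols <- ncol(y)
    box <- matrix(0, nVols, 4,
                  dimnames = list(NULL, unique(sim$blocks$category)))
    for (b in seq_len(nrow(sim$blocks))) {
      v0 <- as.integer(sim$blocks$onset_s[b] / 2)
      box[(v0 + 1):(v0 + 8), sim$blocks$category[b]] <- 1
    }
    h <- boyntonHrf(2)
    X <- cbind(apply(box, 2, convolveHrf, kernel = h), 1)
    psc <- t(apply(y, 1, function(v) 100 * (v - mean(v)) / mean(v)))
    fit <- fitGlm(t(psc), X)
    contrasts <- list(c(1, -1, 0, 0, 0), c(1, 0, -1, 0, 0),
                      c(1, 0, 0, -1, 0))
    tmaps <- lapply(contrasts, function(w) contrastTMap(fit, w))
    sum(conjunctionMask(tmaps, 3))
  })
  expect_lt(mean(survivors), 0.2)
})
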