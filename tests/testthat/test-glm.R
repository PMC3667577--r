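test_that("HRF kernel is causal, unit-sum, and peaks at (n-1)*tau", {
  h <- boyntonHrf(2)
  expect_equal(h[1], 0)          # t <= 0 contributes nothing
  expect_equal(sum(h), 1)
  # grid-search maximum of the analytic gamma form at 1 ms resolution
  tt <- seq(0.001, 15, by = 0.001)
  g <- (tt / 1.2)^2 * exp(-tt / 1.2) / (1.2 * gamma(3))
  expect_equal(tt[which.max(g)], 2.4, tolerance = 1e-3)
  # convolving a constant returns the same constant (unit sum)
  x <- rep(3.7, 60)
  y <- convolveHrf(x, h)
  expect_equal(y[(length(h) + 1):60], rep(3.7, 60 - length(h)),
               tolerance = 1e-10)
  expect_error(boyntonHrf(-1), "positive")
  expect_error(boyntonHrf(2, tauS = 0), "positive")
})

test_that("design matrix boxcars span the declared phase volumes", {
  sch <- makeTrialSchedule(1, 2, seed = 1, effectors = "hand")
  nv <- 2 + 4 * 17
  # identity kernel isolates the raw boxcars
  dm <- buildDesignMatrix(sch, hrf = 1, nVolumesPerRun = nv)
  lb <- dm$labels
  expect_equal(sum(lb$task), 2 * 3)  # 2 conditions x 3 phases in one run
  pre <- dm$matrix[, lb$predictor[lb$phaseName %in% "preview" &
                                  lb$condition == "hand_grasp"]]
  expect_equal(sum(pre != 0), 3 * sum(sch$action == "grasp"))
  pl <- dm$matrix[, lb$predictor[lb$phaseName %in% "plan" &
                                 lb$condition == "hand_grasp"]]
  expect_equal(sum(pl != 0), 6 * sum(sch$action == "grasp"))
  ex <- dm$matrix[, lb$predictor[lb$phaseName %in% "execute" &
                                 lb$condition == "hand_grasp"]]
  expect_equal(sum(ex != 0), 1 * sum(sch$action == "grasp"))
  # two-effector session: 4 conditions x 3 phases = 12 task columns
  sch2 <- makeTrialSchedule(1, 2, seed = 1)
  dm2 <- buildDesignMatrix(sch2, hrf = 1, nVolumesPerRun = nv)
  expect_equal(length(dm2$taskColumns), 12)
})

test_that("convolved design columns match a direct convolution oracle", {
  sch <- makeTrialSchedule(1, 2, seed = 2, effectors = "hand")
  h <- boyntonHrf(2)
  nv <- 2 + 4 * 17
  raw <- buildDesignMatrix(sch, hrf = 1, nVolumesPerRun = nv)
  conv <- buildDesignMatrix(sch, hrf = h, nVolumesPerRun = nv)
  for (j in conv$taskColumns) {
    # brute-force discrete convolution oracle
    b <- raw$matrix[, j]
    oracle <- numeric(nv)
    for (t in seq_len(nv))
      for (l in seq_along(h))
        if (t - l + 1 >= 1) oracle[t] <- oracle[t] + b[t - l + 1] * h[l]
    expect_equal(unname(conv$matrix[, j]), oracle, tolerance = 1e-10)
  }
})

test_that("empty schedules give all-zero task columns", {
  sch <- makeTrialSchedule(1, 2, seed = 1, effectors = "hand")
  sch$error <- TRUE   # all trials routed to no-interest predictors
  dm <- buildDesignMatrix(sch, hrf = boyntonHrf(2),
                          nVolumesPerRun = 2 + 4 * 17)
  taskCols <- dm$labels$predictor[dm$labels$task &
                                  dm$labels$condition != "error"]
  expect_true(all(abs(dm$matrix[, taskCols]) == 0))
})

test_that("OLS recovers noiseless betas exactly and flags rank deficiency", {
  set.seed(4)
  X <- cbind(1, matrix(rnorm(60 * 3), 60, 3))
  colnames(X) <- c("icpt", "a", "b", "c")
  beta <- c(2, -1, 0.5, 3)
  y <- X %*% beta
  fit <- fitGlm(y, X)
  expect_equal(drop(glmBetas(fit)), beta, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(glmDof(fit), 60 - 4)
  # residuals orthogonal to the design
  res <- y - X %*% glmBetas(fit)
  expect_lt(max(abs(crossprod(X, res))), 1e-8)
  # constant series in PSC (all zero) -> all task betas 0
  fit0 <- fitGlm(matrix(0, 60, 2), X)
  expect_true(all(glmBetas(fit0) == 0))
  Xbad <- cbind(X, dup = X[, "a"])
  expect_error(fitGlm(y, Xbad), "rank deficient")
})

test_that("null t maps follow the Student-t distribution", {
  set.seed(5)
  X <- cbind(1, scale(matrix(rnorm(40 * 2), 40, 2)))
  y <- matrix(rnorm(40 * 1000), 40, 1000)
  fit <- fitGlm(y, X)
  tmap <- contrastTMap(fit, c(0, 1, 0))
  ks <- ks.test(tmap, pt, df = glmDof(fit))
  expect_gt(ks$p.value, 0.01)
})

test_that("contrast t matches the closed-form oracle on a random instance", {
  set.seed(6)
  X <- cbind(1, matrix(rnorm(30 * 3), 30, 3))
  y <- matrix(rnorm(30 * 5), 30, 5)
  fit <- fitGlm(y, X)
  w <- c(0, 1, -2, 1)
  tmap <- contrastTMap(fit, w)
  # independent closed-form computation
  bh <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% bh
  s2 <- colSums(res^2) / (30 - 4)
  oracle <- drop(crossprod(w, bh)) /
    sqrt(s2 * drop(t(w) %*% solve(crossprod(X)) %*% w))
  expect_equal(tmap, oracle, tolerance = 1e-10)
  expect_error(contrastTMap(fit, c(1, 2)), "length")
})

test_that("motor contrast weights pool phases and sum to zero", {
  sch <- makeTrialSchedule(1, 2, seed = 1)
  dm <- buildDesignMatrix(sch, hrf = boyntonHrf(2),
                          nVolumesPerRun = 2 + 4 * 17)
  w <- motorContrastWeights(dm)
  expect_equal(sum(w), 0)    # 4(+1) + 4(+1) + 4(-2)
  expect_equal(sum(w == 1), 8)
  expect_equal(sum(w == -2), 4)
  # equal betas across Plan, Execute, Preview -> t = 0
  fit <- fitGlm(dm$matrix %*% rep(1, ncol(dm$matrix)) +
                  0 * rnorm(nrow(dm$matrix)), dm)
  expect_equal(unname(drop(crossprod(w, glmBetas(fit)))), 0,
               tolerance = 1e-8)
})

test_that("conjunction equals the intersection of thresholded maps", {
  set.seed(7)
  maps <- lapply(1:3, function(i) rnorm(300, mean = 3.2))
  conj <- conjunctionMask(maps, threshold = 3)
  oracle <- Reduce(intersect, lapply(maps, function(m) which(m >= 3)))
  expect_equal(which(conj), oracle)
  expect_true(all(which(conj) %in% which(maps[[1]] >= 3)))
  # any one map below threshold excludes the voxel
  m2 <- maps
  m2[[2]][oracle[1]] <- 0
  expect_false(conjunctionMask(m2, 3)[oracle[1]])
  expect_error(conjunctionMask(list()), "at least one")
})

test_that("ROI selection matches a brute-force lattice scan", {
  set.seed(8)
  tmap <- array(rnorm(10 * 10 * 10, mean = 1.5), c(10, 10, 10))
  seed <- c(15, 15, 15)
  roi <- selectRoi(tmap, seed, cubeEdgeMm = 15, tThreshold = 3,
                   minClusterMm3 = 0, voxelSizeMm = 3)
  # exhaustive oracle over every lattice voxel
  centers <- (1:10 - 0.5) * 3
  oracle <- integer(0)
  for (k in 1:10) for (j in 1:10) for (i in 1:10) {
    if (all(abs(c(centers[i], centers[j], centers[k]) - seed) <= 7.5) &&
        tmap[i, j, k] >= 3)
      oracle <- c(oracle, i + 10 * (j - 1 + 10 * (k - 1)))
  }
  expect_setequal(roiVoxels(roi), oracle)
  expect_lte(length(roiVoxels(roi)), 125)   # (15/3)^3 candidates
  expect_true(all(roiTValues(roi) >= 3))
})

test_that("cluster correction removes isolated supra-threshold singletons", {
  tmap <- array(0, c(10, 10, 10))
  tmap[5, 5, 5] <- 10                        # isolated singleton
  tmap[2, 2, 2:6] <- 10                      # 5-voxel face-connected line
  roi <- selectRoi(tmap, c(15, 15, 15), cubeEdgeMm = 30, tThreshold = 3,
                   minClusterMm3 = 113.5, voxelSizeMm = 3)
  # 113.5 mm^3 at 27 mm^3/voxel requires >= 5 voxels: line kept, singleton not
  idx <- arrayInd(roiVoxels(roi), c(10, 10, 10))
  expect_equal(nrow(idx), 5)
  expect_true(all(idx[, 1] == 2))
  suppressWarnings(
    roiEmpty <- selectRoi(array(0, c(5, 5, 5)), c(7, 7, 7)))
  expect_length(roiVoxels(roiEmpty), 0)
})

test_that("control ROIs keep about half of a zero-mean map and are deterministic", {
  set.seed(9)
  props <- replicate(300, {
    tmap <- array(rnorm(125), c(5, 5, 5))
    length(roiVoxels(makeControlRoi(tmap, c(7.5, 7.5, 7.5),
                                    cubeEdgeMm = 15))) / 125
  })
  expect_equal(mean(props), 0.5, tolerance = 0.02)
  tmap <- array(rnorm(125), c(5, 5, 5))
  expect_identical(roiVoxels(makeControlRoi(tmap, c(7.5, 7.5, 7.5))),
                   roiVoxels(makeControlRoi(tmap, c(7.5, 7.5, 7.5))))
  # all-negative map -> empty ROI
  expect_length(roiVoxels(makeControlRoi(array(-1, c(5, 5, 5)),
                                         c(7.5, 7.5, 7.5))), 0)
})
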