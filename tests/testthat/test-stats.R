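test_that("group t test matches the closed form and t.test", {
  acc <- c(0.55, 0.60, 0.50, 0.65, 0.70)
  r <- groupTtestVsChance(acc)
  # hand-computed closed form (mean - 0.5) / (sd / sqrt(5))
  expect_equal(r$t, (mean(acc) - 0.5) / (sd(acc) / sqrt(5)),
               tolerance = 1e-12)
  ref <- t.test(acc, mu = 0.5)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  expect_equal(r$dof, 4)
  # scale equivariance: doubling deviations doubles sd, t unchanged
  acc2 <- 0.5 + 2 * (acc - 0.5)
  expect_equal(groupTtestVsChance(acc2)$t, r$t, tolerance = 1e-12)
  expect_error(groupTtestVsChance(0.6), "2 subjects")
})

test_that("zero-variance accuracies follow the declared convention", {
  r0 <- groupTtestVsChance(rep(0.5, 6))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  r1 <- groupTtestVsChance(rep(0.7, 6))
  expect_equal(r1$t, Inf)
  expect_equal(r1$p, .Machine$double.xmin)
  expect_equal(groupTtestVsChance(rep(0.3, 6))$t, -Inf)
})

test_that("BH mask matches a direct step-up oracle and is monotone", {
  p <- c(0.01, 0.02, 0.03, 0.20)
  mask <- fdrMask(p, q = 0.05)
  # direct Benjamini-Hochberg step-up computation
  bhOracle <- function(p, q) {
    m <- length(p)
    o <- order(p)
    k <- max(c(0, which(p[o] <= q * seq_len(m) / m)))
    out <- rep(FALSE, m)
    if (k > 0) out[o[seq_len(k)]] <- TRUE
    out
  }
  expect_equal(mask, bhOracle(p, 0.05))
  expect_equal(sum(mask), 3)
  expect_true(all(fdrMask(rep(0.001, 10))))
  # monotone: lowering any p never unflags another test
  set.seed(20)
  for (i in 1:20) {
    p <- runif(12)
    m1 <- fdrMask(p, 0.05)
    j <- sample.int(12, 1)
    p2 <- p
    p2[j] <- p[j] / 10
    m2 <- fdrMask(p2, 0.05)
    expect_true(all(m2[m1 & seq_len(12) != j] |
                    !m1[seq_len(12) != j][m1[seq_len(12) != j]]))
    expect_true(all(which(m1) %in% union(which(m2), j)) ||
                all(m2[setdiff(which(m1), j)]))
  }
  expect_error(fdrMask(numeric(0)), "empty")
})

test_that("permutation p uses the add-one estimator and a centred null", {
  f <- gaussianFeatures(8, 4, mu = 3, sd = 0.5, seed = 21)
  obs <- leaveOnePairOut(rescaleFeatures(f$x), f$labels)$accuracy
  r <- permutationPvalue(list(rescaleFeatures(f$x)), list(f$labels),
                         obs, nPerm = 99, seed = 1)
  # observed exceeds every permuted value -> p = 1/(nPerm+1)
  expect_equal(r$p, 1 / 100)
  expect_equal(length(r$null), 99)
  # on no-signal data the permutation null is centred at chance
  f0 <- gaussianFeatures(8, 4, mu = 0, seed = 22)
  r0 <- permutationPvalue(list(rescaleFeatures(f0$x)), list(f0$labels),
                          0.5, nPerm = 99, seed = 2)
  expect_lt(abs(mean(r0$null) - 0.5), 0.05)
  expect_error(permutationPvalue(list(f$x), list(f$labels), 0.6,
                                 nPerm = 10), "99")
})

test_that("GG rmANOVA matches aov and an independent epsilon formula", {
  set.seed(22)
  m <- matrix(rnorm(13 * 3, mean = 0.55, sd = 0.05), 13, 3)
  r <- rmAnovaGG(m)
  # F oracle via aov with subject error stratum
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(1:13, 3)),
                   cond = factor(rep(1:3, each = 13)))
  av <- summary(aov(y ~ cond + Error(subj/cond), data = df))
  Fref <- av[["Error: subj:cond"]][[1]]["cond", "F value"]
  expect_equal(r$F, Fref, tolerance = 1e-8)
  # independent textbook epsilon from the eigenvalues of the
  # contrast-projected covariance
  k <- 3
  Cmat <- stats::contr.helmert(k)
  Cmat <- qr.Q(qr(Cmat))             # orthonormal contrasts
  St <- t(Cmat) %*% cov(m) %*% Cmat
  lam <- eigen(St, symmetric = TRUE, only.values = TRUE)$values
  epsRef <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  expect_equal(r$epsilon, epsRef, tolerance = 1e-8)
  expect_gte(r$epsilon, 1 / (k - 1))
  expect_lte(r$epsilon, 1)
  expect_equal(r$p,
               pf(r$F, 2 * r$epsilon, 24 * r$epsilon, lower.tail = FALSE))
})

test_that("degenerate rmANOVA inputs follow the declared conventions", {
  m <- matrix(rep(c(0.5, 0.6, 0.7), each = 5), 5, 3)  # identical columns
  mIdent <- matrix(0.6, 5, 3)
  r <- rmAnovaGG(mIdent)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  expect_error(rmAnovaGG(matrix(c(1, 2, NA, 4, 5, 6), 3, 2)), "missing")
  expect_error(rmAnovaGG(matrix(1:4, 2, 2)), "3 subjects")
})

test_that("paired follow-ups equal one-sample t on differences with BH flags", {
  set.seed(23)
  m <- matrix(rnorm(10 * 3, 0.55, 0.04), 10, 3,
              dimnames = list(NULL, c("hand", "tool", "cross")))
  m[, 1] <- m[, 1] + 0.1
  r <- pairedFollowups(m)
  expect_equal(nrow(r), 3)           # k(k-1)/2 pairs
  for (i in seq_len(nrow(r))) {
    ref <- t.test(m[, r$conditionA[i]], m[, r$conditionB[i]],
                  paired = TRUE)
    expect_equal(r$t[i], unname(ref$statistic), tolerance = 1e-8)
    expect_equal(r$p[i], ref$p.value, tolerance = 1e-8)
  }
  # identical columns give t = 0, p = 1
  m2 <- cbind(a = m[, 1], b = m[, 1], c = m[, 2])
  r2 <- pairedFollowups(m2)
  row <- r2[r2$conditionA == "a" & r2$conditionB == "b", ]
  expect_equal(row$t, 0)
  expect_equal(row$p, 1)
})

test_that("the profile decision table maps evidence to labels", {
  expect_equal(profileFromEvidence(TRUE, FALSE, FALSE, FALSE),
               "hand_specific")
  expect_equal(profileFromEvidence(TRUE, FALSE, TRUE, TRUE),
               "hand_specific")      # cross ignored without both effectors
  expect_equal(profileFromEvidence(FALSE, TRUE, FALSE, FALSE),
               "tool_specific")
  expect_equal(profileFromEvidence(TRUE, TRUE, FALSE, TRUE),
               "effector_specific_both")
  expect_equal(profileFromEvidence(TRUE, TRUE, TRUE, FALSE),
               "effector_independent")
  expect_equal(profileFromEvidence(FALSE, FALSE, FALSE, TRUE),
               "execute_only")
  expect_equal(profileFromEvidence(FALSE, FALSE, TRUE, FALSE), "null")
  expect_equal(profileFromEvidence(FALSE, FALSE, FALSE, FALSE), "null")
})

test_that("classifyCodingProfile reads flags from a DecodingResult", {
  # build a synthetic result with known significance structure
  set.seed(24)
  mk <- function(handPlan, toolPlan, crossPlan, execAcc) {
    accs <- lapply(1:8, function(s) {
      a <- matrix(0.5 + rnorm(3 * 18, 0, 0.01), 3, 18,
                  dimnames = list(c("hand_GvsR", "tool_GvsR",
                                    "cross_effector"),
                                  c(paste0("t", 1:17), "plan")))
      if (handPlan) a["hand_GvsR", "plan"] <- 0.8 + rnorm(1, 0, 0.01)
      if (toolPlan) a["tool_GvsR", "plan"] <- 0.8 + rnorm(1, 0, 0.01)
      if (crossPlan) a["cross_effector", "plan"] <- 0.8 + rnorm(1, 0, 0.01)
      if (execAcc) {
        a["hand_GvsR", "t11"] <- 0.85 + rnorm(1, 0, 0.01)
        a["tool_GvsR", "t12"] <- 0.85 + rnorm(1, 0, 0.01)
      }
      pmin(pmax(a, 0), 1)
    })
    groupDecoding(accs, roi = "test")
  }
  expect_equal(profileLabel(classifyCodingProfile(mk(TRUE, FALSE, FALSE,
                                                     FALSE))),
               "hand_specific")
  expect_equal(profileLabel(classifyCodingProfile(mk(TRUE, TRUE, TRUE,
                                                     FALSE))),
               "effector_independent")
  expect_equal(profileLabel(classifyCodingProfile(mk(TRUE, TRUE, FALSE,
                                                     FALSE))),
               "effector_specific_both")
  expect_equal(profileLabel(classifyCodingProfile(mk(FALSE, FALSE, FALSE,
                                                     TRUE))),
               "execute_only")
  # a result without the plan epoch cannot be classified
  accs <- lapply(1:4, function(s)
    matrix(0.5, 3, 2, dimnames = list(c("hand_GvsR", "tool_GvsR",
                                        "cross_effector"),
                                      c("t8", "t9"))))
  resNoPlan <- groupDecoding(accs, roi = "x")
  expect_error(classifyCodingProfile(resNoPlan), "missing plan-epoch")
})

test_that("groupDecoding assembles accuracies and one per-ROI FDR family", {
  set.seed(25)
  accs <- lapply(1:6, function(s)
    matrix(runif(3 * 4, 0.4, 0.6), 3, 4,
           dimnames = list(c("hand_GvsR", "tool_GvsR", "cross_effector"),
                           c("t8", "t9", "t10", "plan"))))
  res <- groupDecoding(accs, roi = "spoc")
  expect_equal(dim(accuracies(res)), c(6L, 3L, 4L))
  gs <- groupStats(res)
  expect_equal(nrow(gs), 12)
  expect_equal(gs$fdrSignificant, fdrMask(gs$p, 0.05))
})
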