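# Small fixture builders shared across the suite.  Everything is
# generated in code at test time; no data files.

tinyConfig <- function(schemeName = "null", amplitude = 0,
                       informativeFraction = 0.5, nRuns = 1, reps = 3,
                       nVoxels = 8, noiseSd = 1, seed = 1, ...) {
  generatorConfig(nSubjects = 1, nRunsPerEffector = nRuns,
                  trialsPerCondition = reps, nVoxels = nVoxels,
                  noiseSd = noiseSd, seed = seed,
                  roiSchemes = list(roi = codingScheme(
                    schemeName, amplitude, informativeFraction)), ...)
}

# deterministic two-class gaussian features: class means +/- mu on the
# first nInf voxels
gaussianFeatures <- function(nPerClass, nVox, mu, nInf = nVox, sd = 1,
                             seed = 1) {
  set.seed(seed)
  labels <- rep(c("grasp", "reach"), each = nPerClass)
  shift <- c(rep(mu, nInf), rep(0, nVox - nInf))
  x <- matrix(rnorm(2 * nPerClass * nVox, sd = sd), ncol = nVox)
  x[labels == "grasp", ] <- sweep(x[labels == "grasp", , drop = FALSE],
                                  2, shift, "+")
  x[labels == "reach", ] <- sweep(x[labels == "reach", , drop = FALSE],
                                  2, shift, "-")
  list(x = x, labels = labels)
}

# mean grasp-minus-reach pattern difference of a feature matrix
conditionDiff <- function(fm) {
  x <- featureValues(fm)
  y <- featureLabels(fm)
  colMeans(x[y == "grasp", , drop = FALSE]) -
    colMeans(x[y == "reach", , drop = FALSE])
}
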