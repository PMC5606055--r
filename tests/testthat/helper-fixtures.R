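# Shared fixtures, built in code at test time.

# The published 16-feature sensitivity column, in its printed feature order.
referenceSensitivities <- function() {
  c(age = 0.081, sex = 0.008, BMI = 0.038, To_chole = 0.100, HDL = 0.013,
    SBP = 0.073, DBP = 0.049, triglyceride = 0.013, hemoglobin = 0.006,
    TD = 0.003, CRF = 0.010, H_B = 0.001, H_C = 0.001, cirrhosis = 0.002,
    smoking = 0.012, diabetes = 0.024)
}

referenceFeatureOrder <- function() names(referenceSensitivities())

refMatrixPath <- function() {
  system.file("extdata", "chd_sensitivity_change_reference.csv", package = "nnfca")
}

refEliminationPath <- function() {
  system.file("extdata", "chd_elimination_accuracy_reference.csv", package = "nnfca")
}

# Two continuous features + binary outcome, no categorical complications.
toySpecs <- function(n = 2) {
  lapply(seq_len(n), function(k)
    featureSpec(paste0("x", k), "continuous", validRange = c(0, 1)))
}

toyTable <- function(X, y) {
  cohortTable(X, y, toySpecs(ncol(X)))
}

# A linearly separable scaled 2-feature cohort with a margin around the
# decision boundary x1 + x2 = 1.
separableTable <- function(n = 60, seed = 42) {
  X <- withr::with_seed(seed, {
    cand <- matrix(runif(8 * n), ncol = 2)
    cand[abs(rowSums(cand) - 1) > 0.15, , drop = FALSE][seq_len(n), ]
  })
  y <- as.integer(X[, 1] + X[, 2] > 1)
  scaleFeatures(toyTable(X, y), params = list(
    x1 = list(lo = 0, hi = 1, constant = FALSE),
    x2 = list(lo = 0, hi = 1, constant = FALSE)))
}

# Hand-set 1-1-1 network: input weight v, hidden bias b, output weight w,
# output bias c.
handNetwork111 <- function(v = 1, b = 0, w = 1, c = 0) {
  spec <- networkSpec("x1", nHidden = 1L)
  new("TrainedNetwork", spec = spec, W = matrix(v, 1, 1), bHidden = b,
      wOut = w, bOut = c, config = list(), lossHistory = numeric(0))
}

# Hand-set 2-input, 1-hidden network; both features feed the hidden unit.
handNetwork211 <- function(v = c(1, -0.5), b = 0.2, w = 1.5, c = -0.1) {
  spec <- networkSpec(c("x1", "x2"), nHidden = 1L)
  new("TrainedNetwork", spec = spec, W = matrix(v, 2, 1), bHidden = b,
      wOut = w, bOut = c, config = list(), lossHistory = numeric(0))
}

# Write a small cohort CSV with optional missing rows / under-age rows.
writeToyCsv <- function(path, rows) {
  header <- paste(c("age", "BMI", "chd_risk"), collapse = ",")
  writeLines(c(header, rows), path)
  path
}

# Small simulated config: 2 strong informative features, 3 pure-noise.
plantedConfig <- function(n = 600, seed = 1) {
  cont <- function(name) list(name = name, kind = "continuous",
                              mean = 0.5, sd = 0.2, lo = 0, hi = 1)
  simulationConfig(
    nRecords = n,
    features = lapply(paste0(c("inf", "inf", "noise", "noise", "noise"),
                             c(1, 2, 1, 2, 3)), cont),
    effects = c(inf1 = 4, inf2 = 4),
    intercept = -4,
    seed = seed
  )
}
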