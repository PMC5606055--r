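test_that("confusion metrics follow the predictive-value identities", {
  r <- confusionMetrics(c(1, 0), c(0.9, 0.1))
  expect_equal(c(r@ppv, r@npv, r@accuracy), c(100, 100, 100))

  # TP=2 FP=1 FN=1 TN=2
  labels <- c(1, 1, 0, 1, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.3, 0.1)
  r2 <- confusionMetrics(labels, scores)
  expect_equal(unname(confusionCounts(r2)), c(2L, 1L, 1L, 2L))
  expect_equal(r2@ppv, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(r2@npv, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(r2@accuracy, 100 * 4 / 6, tolerance = 1e-12)

  # undefined PPV when nothing is predicted positive
  r3 <- confusionMetrics(c(1, 0), c(0.1, 0.2), threshold = 0.9)
  expect_true(is.na(r3@ppv))
  expect_true("ppv_undefined" %in% r3@flags)
  expect_error(confusionMetrics(c(1, 0), c(0.5, 0.5, 0.5)), "align")
  expect_error(confusionMetrics(c(1, 0), c(0.5, 0.5), threshold = 1), "threshold")
})

test_that("confusion metrics equal brute-force cell counting on random fixtures", {
  for (r in 1:50) {
    n <- withr::with_seed(r, sample(5:50, 1))
    labels <- withr::with_seed(r + 100, rbinom(n, 1, 0.4))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- withr::with_seed(r + 200, runif(n))
    rep <- confusionMetrics(labels, scores)
    bc <- bruteCounts(labels, scores, 0.5)
    expect_equal(unname(confusionCounts(rep)), unname(bc))
    expect_equal(rep@accuracy, 100 * (bc["tp"] + bc["tn"]) / n,
                 ignore_attr = TRUE)
  }
})

test_that("AUC equals exhaustive pair counting, handles ties, and is
           invariant under monotone transforms", {
  expect_equal(rocAuc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(rocAuc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(rocAuc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2)), 0.75)
  expect_equal(rocAuc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2)),
               bruteAuc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2)))

  for (r in 1:30) {
    n <- withr::with_seed(r, sample(4:50, 1))
    labels <- c(0, 1, withr::with_seed(r + 1, rbinom(n - 2, 1, 0.5)))
    scores <- withr::with_seed(r + 2, round(runif(n), 1))  # force ties
    a <- rocAuc(labels, scores)
    expect_equal(a, bruteAuc(labels, scores))
    expect_equal(rocAuc(labels, exp(3 * scores) + 1), a)  # monotone transform
  }
  expect_error(rocAuc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  labels <- withr::with_seed(31, rbinom(200, 1, 0.3))
  scores <- withr::with_seed(32, runif(200))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rocAuc(labels, scores), ref, tolerance = 1e-12)
})

test_that("bootstrap CI is seeded, degenerate on separated data, and covers
           a known AUC", {
  labels <- rep(c(1, 0), each = 250)
  sep <- c(runif(250, 0.8, 1), runif(250, 0, 0.2))
  ci <- aucCi(labels, sep, nBoot = 200, seed = 1)
  expect_identical(ci, aucCi(labels, sep, nBoot = 200, seed = 1))
  expect_lt(ci[2] - ci[1], 0.01)
  expect_true(ci[1] <= 1 && 1 <= ci[2])
  expect_error(aucCi(labels, sep, nBoot = 50), "100")

  # coverage: binormal scores with true AUC 0.75
  mu <- sqrt(2) * qnorm(0.75)
  cover <- 0
  for (r in 1:100) {
    y <- rep(c(0, 1), each = 500)
    sc <- withr::with_seed(1000 + r, c(rnorm(500), rnorm(500, mu)))
    interval <- aucCi(y, sc, nBoot = 200, seed = r)
    if (interval[1] <= 0.75 && 0.75 <= interval[2]) cover <- cover + 1
  }
  expect_gte(cover, 90)
})

test_that("logistic baseline flags separation and scores perfectly on a
           separable toy set", {
  tab <- separableTable()
  fit <- fitLogisticBaseline(tab, tab)
  expect_equal(fit$report@accuracy, 100)
  expect_true("separation" %in% fit$report@flags)
})

test_that("logistic baseline is near chance when outcome is independent of
           features", {
  cont <- function(name) list(name = name, kind = "continuous",
                              mean = 0.5, sd = 0.2, lo = 0, hi = 1)
  cfg <- simulationConfig(2000, lapply(paste0("x", 1:4), cont),
                          intercept = 0, seed = 11)
  tab <- scaleFeatures(simulateCohort(cfg)$table)
  sp <- splitTrainValidation(tab, 0.7, 1)
  fit <- fitLogisticBaseline(sp$train, sp$validation)
  expect_gte(fit$report@auc, 0.45)
  expect_lte(fit$report@auc, 0.55)
})

test_that("logistic baseline recovers a known coefficient within 10 percent", {
  n <- 20000
  x <- withr::with_seed(5, runif(n))
  y <- withr::with_seed(6, rbinom(n, 1, plogis(-1 + 3 * x)))
  tab <- scaleFeatures(
    cohortTable(matrix(x, ncol = 1), y,
                list(featureSpec("x1", "continuous", validRange = c(0, 1)))),
    params = list(x1 = list(lo = 0, hi = 1, constant = FALSE)))
  fit <- fitLogisticBaseline(tab, tab)
  expect_lt(abs(fit$coefficients[["x1"]] - 3) / 3, 0.1)
})

test_that("the comparison table carries one row per model", {
  r <- confusionMetrics(c(1, 0, 1, 0), c(0.9, 0.2, 0.4, 0.6))
  tbl <- metricsTable(list(lr = r, nn = r, nnfca = r))
  expect_equal(nrow(tbl), 3)
  expect_named(tbl, c("model", "PPV", "NPV", "Accuracy", "AUC",
                      "AUC_lower", "AUC_upper"))
  parsed <- jsonlite::fromJSON(writeMetricsJson(r))
  expect_equal(parsed$tp + parsed$fp + parsed$fn + parsed$tn, 4)
})
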