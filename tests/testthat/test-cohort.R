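test_that("exclusion rules count missing-first, then age, each record once", {
  csv <- withr::local_tempfile(fileext = ".csv")
  rows <- c(
    "45,22.1,0", "51,Null,1", "63,27.0,1", ",24.2,0", "38,21.5,0",
    "25,23.3,0",  # under age, no missing
    "70,26.4,1", "55,25.0,0", "47,23.8,1", "33,20.9,0"
  )
  writeToyCsv(csv, rows)
  specs <- list(featureSpec("age", "continuous", validRange = c(0, 120)),
                featureSpec("BMI", "continuous", validRange = c(10, 60)))
  res <- loadCohort(csv, specs)
  expect_s4_class(res$exclusion, "ExclusionReport")
  expect_equal(res$exclusion@nRaw, 10L)
  expect_equal(res$exclusion@nExcludedMissing, 2L)
  expect_equal(res$exclusion@nExcludedAge, 1L)
  expect_equal(res$exclusion@nFinal, 7L)
  expect_equal(nRecords(res$table), 7L)

  # identity case: nothing excluded
  csv2 <- withr::local_tempfile(fileext = ".csv")
  writeToyCsv(csv2, c("45,22.1,0", "51,24.0,1", "63,27.0,1"))
  res2 <- loadCohort(csv2, specs)
  expect_equal(res2$exclusion@nFinal, res2$exclusion@nRaw)

  # a record violating both rules is counted once, in the missing rule
  csv3 <- withr::local_tempfile(fileext = ".csv")
  writeToyCsv(csv3, c("25,Null,0", "45,22.0,1", "50,21.0,0"))
  res3 <- loadCohort(csv3, specs)
  expect_equal(res3$exclusion@nExcludedMissing, 1L)
  expect_equal(res3$exclusion@nExcludedAge, 0L)
})

test_that("schema and degenerate inputs raise errors", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeToyCsv(csv, c("45,22.1,0"))
  specs <- c(toySpecs(1), list(featureSpec("age", "continuous")))
  expect_error(loadCohort(csv, specs), "schema error")
  csvEmpty <- withr::local_tempfile(fileext = ".csv")
  writeToyCsv(csvEmpty, c("25,22.1,0", "29,23.0,1"))
  expect_error(
    loadCohort(csvEmpty, list(featureSpec("age", "continuous"),
                              featureSpec("BMI", "continuous"))),
    "degenerate")
  # exclusion arithmetic identity is enforced by the class itself
  expect_error(new("ExclusionReport", nRaw = 10L, nExcludedMissing = 2L,
                   nExcludedAge = 1L, nFinal = 6L), "nFinal")
})

test_that("outcome derives from component-disease flags (any-of-five rule)", {
  flags <- rbind(c(0, 0, 0, 0, 0),
                 c(0, 0, 1, 0, 0),
                 c(1, 1, 1, 1, 1))
  expect_equal(deriveOutcome(flags), c(0L, 1L, 1L))
  expect_error(deriveOutcome(rbind(c(0, 2, 0, 0, 0))), "0/1")

  # the five columns are picked up when no outcome column exists
  csv <- withr::local_tempfile(fileext = ".csv")
  header <- paste(c("age", componentDiseaseColumns()), collapse = ",")
  writeLines(c(header, "45,0,0,0,0,0", "60,0,1,0,0,0"), csv)
  res <- loadCohort(csv, list(featureSpec("age", "continuous")))
  expect_equal(outcome(res$table), c(0L, 1L))
})

test_that("min-max scaling maps continuous, binary and ordinal features to [0,1]", {
  specs <- list(featureSpec("age", "continuous", validRange = c(0, 120)),
                featureSpec("smoking", "binary", levels = c("no", "yes")),
                featureSpec("diabetes", "ordinal",
                            levels = c("no", "ifg", "diabetes")))
  values <- cbind(age = c(30, 61, 92), smoking = c(0, 1, 1),
                  diabetes = c(0, 1, 2))
  tab <- scaleFeatures(cohortTable(values, c(0, 1, 1), specs))
  expect_equal(unname(featureMatrix(tab)[2, "age"]), 0.5)      # midpoint of 30..92
  expect_equal(unname(featureMatrix(tab)[2, "smoking"]), 1.0)  # level "yes"
  expect_equal(unname(featureMatrix(tab)[2, "diabetes"]), 0.5) # middle of 3 levels
  expect_true(isScaled(tab))

  # idempotent when reapplied with the same parameters
  expect_identical(scaleFeatures(tab, scalingParams(tab)), tab)

  # training-set params reused on new data
  newTab <- cohortTable(cbind(age = 45.5, smoking = 0, diabetes = 0),
                        1L, specs)
  rescaled <- scaleFeatures(newTab, scalingParams(tab))
  expect_equal(unname(featureMatrix(rescaled)[1, "age"]), (45.5 - 30) / 62)
})

test_that("constant features scale to zero with a warning", {
  tab <- toyTable(cbind(x1 = c(0.3, 0.3, 0.3), x2 = c(0, 0.5, 1)), c(0, 1, 1))
  expect_warning(scaled <- scaleFeatures(tab), "constant")
  expect_equal(unname(featureMatrix(scaled)[, "x1"]), c(0, 0, 0))
})

test_that("stratified split is disjoint, exhaustive, reproducible and balanced", {
  y <- c(rep(1L, 50), rep(0L, 50))
  tab <- toyTable(matrix(runif(200), 100, 2), y)
  sp <- splitTrainValidation(tab, 0.7, seed = 3)
  expect_equal(nRecords(sp$train), 70L)
  expect_equal(nRecords(sp$validation), 30L)
  expect_setequal(c(sp$train@ids, sp$validation@ids), tab@ids)

  sp2 <- splitTrainValidation(tab, 0.7, seed = 3)
  expect_identical(sp$train@ids, sp2$train@ids)

  # 80/20 class mix at fraction 0.5: each split gets 40/10 of the classes
  y2 <- c(rep(1L, 20), rep(0L, 80))
  tab2 <- toyTable(matrix(runif(200), 100, 2), y2)
  sp3 <- splitTrainValidation(tab2, 0.5, seed = 1)
  expect_equal(sum(outcome(sp3$train) == 1), 10)
  expect_equal(sum(outcome(sp3$train) == 0), 40)
  expect_error(splitTrainValidation(tab, 1.2), "fraction")
})

test_that("load -> scale -> split round-trips feature names and record counts", {
  csv <- withr::local_tempfile(fileext = ".csv")
  set.seed(8)
  rows <- sprintf("%d,%.1f,%d", sample(30:80, 40, TRUE),
                  runif(40, 18, 35), rbinom(40, 1, 0.4))
  writeToyCsv(csv, rows)
  specs <- list(featureSpec("age", "continuous", validRange = c(0, 120)),
                featureSpec("BMI", "continuous", validRange = c(10, 60)))
  res <- loadCohort(csv, specs)
  tab <- scaleFeatures(res$table)
  sp <- splitTrainValidation(tab, 0.7, 1)
  expect_identical(featureNames(sp$train), c("age", "BMI"))
  expect_identical(featureNames(sp$validation), c("age", "BMI"))
  expect_equal(nRecords(sp$train) + nRecords(sp$validation), nRecords(tab))

  # CSV write/read round trip preserves values and outcome
  out <- withr::local_tempfile(fileext = ".csv")
  writeCohortCsv(tab, out)
  back <- loadCohort(out, list(featureSpec("age", "continuous"),
                               featureSpec("BMI", "continuous")),
                     ageFeature = NULL)
  expect_equal(nRecords(back$table), nRecords(tab))
  expect_equal(outcome(back$table), outcome(tab))
})

test_that("exclusion report serializes to JSON with the identity intact", {
  rep <- new("ExclusionReport", nRaw = 10L, nExcludedMissing = 2L,
             nExcludedAge = 1L, nFinal = 7L)
  parsed <- jsonlite::fromJSON(writeExclusionJson(rep))
  expect_equal(parsed$n_final, parsed$n_raw - parsed$n_excluded_missing -
                 parsed$n_excluded_age)
})
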