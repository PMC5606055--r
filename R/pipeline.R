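#' Run the full risk-prediction workflow
#'
#' Executes, fully seeded: scale -> stratified split -> dense-network
#' training -> sensitivity profile -> stepwise elimination -> best-stage
#' feature selection -> retraining on the selected features -> amplification
#' sensitivity-change matrix -> candidate thresholding -> mutual pairs ->
#' coupled-connection mask -> structured-network training -> evaluation of
#' the logistic-regression, dense-network and structured-network models on
#' the shared validation split. The correlation stage runs on the
#' post-selection feature set.
#'
#' @param x a [CohortTable-class] or a [simulationConfig()] (simulated on the
#'   fly); a list as returned by [loadCohort()] is also accepted, in which
#'   case the exclusion report is carried into the result.
#' @param trainConfig a [trainingConfig()].
#' @param pert a [perturbationSpec()].
#' @param splitSeed seed of the stratified split.
#' @param fraction training fraction.
#' @param nHidden hidden units of the dense networks.
#' @param maxRemove elimination stages; default F - 2.
#' @param hiddenPerGroup hidden units per correlation group in the structured
#'   network.
#' @param threshold classification cutoff.
#' @param nBoot bootstrap resamples for AUC confidence intervals (0 skips).
#' @param candidateTol tolerance of the candidate threshold (0 for computed
#'   full-precision matrices; see [columnCandidates()]).
#' @return a [PipelineReport-class].
#' @export
runPipeline <- function(x, trainConfig = trainingConfig(),
                        pert = perturbationSpec(), splitSeed = 20170906L,
                        fraction = 0.7, nHidden = 4L, maxRemove = NULL,
                        hiddenPerGroup = 1L, threshold = 0.5, nBoot = 200L,
                        candidateTol = 0) {
  exclusion <- NULL
  truth <- NULL
  if (inherits(x, "nnfca_simulationConfig")) {
    sim <- simulateCohort(x)
    table <- sim$table
    truth <- sim$truth
  } else if (is(x, "CohortTable")) {
    table <- x
  } else if (is.list(x) && is(x$table, "CohortTable")) {
    table <- x$table
    exclusion <- x$exclusion
  } else {
    stop("x must be a CohortTable, a simulationConfig, or a loadCohort() result")
  }
  stopifnot(is(table, "CohortTable"))
  if (length(unique(outcome(table))) < 2)
    stop("pipeline stage 'input': outcome must contain both classes")

  table <- scaleFeatures(table)
  split <- splitTrainValidation(table, fraction, splitSeed)
  fn <- featureNames(table)

  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
    message(sprintf("[nnfca] %-12s %6.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  denseNet <- stage("train-dense", {
    net <- initNetwork(networkSpec(fn, nHidden), trainConfig)
    trainNetwork(net, split$train, trainConfig)
  })
  profile <- stage("sensitivity",
    sensitivityProfile(denseNet, split$train, pert))
  if (is.null(maxRemove)) maxRemove <- length(fn) - 2L
  trace <- stage("eliminate",
    stepwiseEliminate(table, trainConfig, pert, maxRemove, fraction,
                      splitSeed, nHidden, threshold))
  best <- selectBestStage(trace)
  selected <- best$selectedFeatures

  selNet <- stage("train-selected", {
    net <- initNetwork(networkSpec(selected, nHidden), trainConfig)
    trainNetwork(net, split$train[, selected], trainConfig)
  })
  changeMatrix <- stage("correlate",
    sensitivityChangeMatrix(selNet, split$train[, selected], pert))
  candidates <- columnCandidates(changeMatrix, candidateTol)
  graph <- mutualPairs(candidates)
  structuredSpec <- buildGroupMask(graph, hiddenPerGroup)

  structuredNet <- stage("train-coupled", {
    net <- initNetwork(structuredSpec, trainConfig)
    trainNetwork(net, split$train[, selected], trainConfig)
  })

  metrics <- stage("evaluate", {
    lr <- fitLogisticBaseline(split$train, split$validation, threshold,
                              nBoot, trainConfig$seed)
    list(
      lr = lr$report,
      nn = evaluateNetwork(denseNet, split$validation, threshold, nBoot,
                           trainConfig$seed),
      nnfca = evaluateNetwork(structuredNet, split$validation[, selected],
                              threshold, nBoot, trainConfig$seed)
    )
  })
  trainingMetrics <- list(
    lr = fitLogisticBaseline(split$train, split$train, threshold)$report,
    nn = evaluateNetwork(denseNet, split$train, threshold),
    nnfca = evaluateNetwork(structuredNet, split$train[, selected], threshold)
  )

  new("PipelineReport", exclusion = exclusion, profile = profile,
      trace = trace, selectedFeatures = selected, changeMatrix = changeMatrix,
      graph = graph, structuredSpec = structuredSpec, metrics = metrics,
      trainingMetrics = trainingMetrics, truth = truth,
      seeds = list(split = splitSeed, training = trainConfig$seed,
                   perturbation = pert$seed))
}

#' @describeIn PipelineReport features surviving the elimination stage
#' @param x a PipelineReport
#' @export
setMethod("selectedFeatures", "PipelineReport", function(x) x@selectedFeatures)

#' @describeIn PipelineReport named list of per-model [MetricsReport-class]
#' @export
setMethod("modelMetrics", "PipelineReport", function(x) x@metrics)

#' @describeIn PipelineReport mutual correlated pairs found on the selected
#'   features
#' @export
setMethod("correlatedPairs", "PipelineReport", function(x) x@graph@pairs)

setMethod("show", "PipelineReport", function(object) {
  cat("PipelineReport\n")
  cat("  selected features (", length(object@selectedFeatures), "): ",
      paste(object@selectedFeatures, collapse = ", "), "\n", sep = "")
  cat("  correlated pairs: ",
      if (nrow(object@graph@pairs) == 0) "none"
      else paste(apply(object@graph@pairs, 1, paste, collapse = "--"),
                 collapse = ", "), "\n", sep = "")
  print(metricsTable(object@metrics))
})
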