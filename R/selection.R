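#' Stepwise elimination of the least-sensitive feature with retraining
#'
#' At each stage a dense network is trained on the remaining features, the
#' sensitivity profile is computed on the training split, the lowest-ranked
#' feature is removed, and the retrained network's accuracy on the shared
#' validation split is recorded. Sensitivities are recomputed after every
#' removal (the remaining-feature network changes), so ranks are never frozen
#' from the first profile. The curve is computed out to `maxRemove` stages;
#' use [selectBestStage()] to pick the peak.
#'
#' @param table a scaled [CohortTable-class] (the split happens inside).
#' @param trainConfig a [trainingConfig()].
#' @param pert a [perturbationSpec()].
#' @param maxRemove number of stages (< number of features).
#' @param fraction training fraction for the internal split.
#' @param splitSeed seed for the stratified split.
#' @param nHidden hidden units of the per-stage dense networks.
#' @param threshold classification cutoff for the accuracy.
#' @return an [EliminationTrace-class]. If retraining at some stage fails
#'   (e.g. class collapse) the curve is truncated at the previous stage with
#'   a warning.
#' @export
stepwiseEliminate <- function(table, trainConfig = trainingConfig(),
                              pert = perturbationSpec(), maxRemove,
                              fraction = 0.7, splitSeed = 20170906L,
                              nHidden = 4L, threshold = 0.5) {
  stopifnot(is(table, "CohortTable"))
  if (!isScaled(table)) stop("table must be scaled before elimination")
  fn <- featureNames(table)
  if (maxRemove >= length(fn)) stop("maxRemove must be < number of features")
  split <- splitTrainValidation(table, fraction, splitSeed)

  fitStage <- function(feats) {
    net <- initNetwork(networkSpec(feats, nHidden), trainConfig)
    net <- trainNetwork(net, split$train[, feats], trainConfig)
    list(net = net,
         accuracy = networkAccuracy(net, split$validation[, feats], threshold))
  }

  stage <- fitStage(fn)
  baseline <- stage$accuracy
  remaining <- fn
  removed <- character(0)
  accuracy <- numeric(0)
  for (k in seq_len(maxRemove)) {
    profile <- sensitivityProfile(stage$net, split$train[, remaining], pert)
    worst <- profile@featureNames[which.max(profile@rank)]
    remaining <- setdiff(remaining, worst)
    stage <- tryCatch(fitStage(remaining), error = function(e) e)
    if (inherits(stage, "error")) {
      warning("stage ", k, " failed (", conditionMessage(stage),
              "); curve truncated")
      break
    }
    removed <- c(removed, worst)
    accuracy <- c(accuracy, stage$accuracy)
  }
  new("EliminationTrace", featureNames = fn, removed = removed,
      accuracy = accuracy, baselineAccuracy = baseline)
}

#' Build an elimination trace from an externally supplied accuracy curve
#'
#' Replay mode: injects a printed accuracy sequence (and, when known, the
#' removal order) so the stage-selection rule can be exercised as a pure
#' function of its inputs.
#'
#' @param accuracies per-stage accuracies (percent), stage k = k features
#'   removed.
#' @param removedFeatures features in removal order (defaults to placeholder
#'   names).
#' @param featureNames full feature set, when known.
#' @param baselineAccuracy the all-features accuracy, or NA when not supplied.
#' @return an [EliminationTrace-class].
#' @export
replayEliminationTrace <- function(accuracies, removedFeatures = NULL,
                                   featureNames = character(0),
                                   baselineAccuracy = NA_real_) {
  if (is.null(removedFeatures))
    removedFeatures <- if (length(accuracies))
      paste0("removed_", seq_along(accuracies)) else character(0)
  new("EliminationTrace", featureNames = featureNames,
      removed = removedFeatures, accuracy = as.numeric(accuracies),
      baselineAccuracy = baselineAccuracy)
}

#' Read a replay accuracy curve from CSV
#'
#' Expects columns `removed_feature` and `accuracy` (one row per stage, in
#' removal order); an optional `feature` order is inferred from context.
#'
#' @param path CSV path.
#' @param featureNames full feature set, when known.
#' @export
readEliminationCsv <- function(path, featureNames = character(0)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  replayEliminationTrace(df$accuracy, df$removed_feature, featureNames)
}

#' Write an elimination trace as CSV
#' @param trace an [EliminationTrace-class].
#' @param path output path.
#' @export
writeEliminationCsv <- function(trace, path) {
  k <- seq_along(trace@removed)
  df <- data.frame(stage = k, removed_feature = trace@removed,
                   cumulative_removed = vapply(k, function(i)
                     paste(trace@removed[seq_len(i)], collapse = ";"), ""),
                   accuracy = trace@accuracy)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pick the best elimination stage
#'
#' Returns the stage with maximum validation accuracy over the whole curve
#' (including the all-features baseline when it is available); ties break
#' toward fewer removed features.
#'
#' @param trace an [EliminationTrace-class].
#' @return list with `selectedFeatures` (character; NA-free only when the
#'   trace knows its full feature set), `nRemoved` and `accuracy`.
#' @export
selectBestStage <- function(trace) {
  stopifnot(is(trace, "EliminationTrace"))
  acc <- trace@accuracy
  nStage <- length(acc)
  if (nStage == 0 && is.na(trace@baselineAccuracy))
    stop("empty trace: nothing to select")
  candRemoved <- seq_len(nStage)
  candAcc <- acc
  if (!is.na(trace@baselineAccuracy)) {
    candRemoved <- c(0L, candRemoved)
    candAcc <- c(trace@baselineAccuracy, candAcc)
  }
  best <- candRemoved[which.max(candAcc)]  # which.max is first-max: fewer removed wins ties
  selected <- if (length(trace@featureNames))
    setdiff(trace@featureNames, trace@removed[seq_len(best)])
  else character(0)
  list(selectedFeatures = selected, nRemoved = as.integer(best),
       accuracy = max(candAcc))
}

#' @describeIn EliminationTrace features in removal order
#' @param x an EliminationTrace
#' @export
setMethod("removedFeatures", "EliminationTrace", function(x) x@removed)

#' @describeIn EliminationTrace per-stage accuracies (percent)
#' @export
setMethod("stageAccuracies", "EliminationTrace", function(x) x@accuracy)

#' @describeIn EliminationTrace all-features accuracy (NA for replayed curves
#'   that do not carry it)
#' @export
setMethod("baselineAccuracy", "EliminationTrace", function(x) x@baselineAccuracy)

#' @describeIn EliminationTrace full feature set the trace started from
#' @export
setMethod("featureNames", "EliminationTrace", function(x) x@featureNames)

setMethod("show", "EliminationTrace", function(object) {
  cat("EliminationTrace:", length(object@removed), "stages, baseline",
      if (is.na(object@baselineAccuracy)) "n/a"
      else sprintf("%.3f%%", object@baselineAccuracy), "\n")
  if (length(object@removed)) {
    for (k in seq_along(object@removed))
      cat(sprintf("  -%d (%s): %.3f%%\n", k, object@removed[k], object@accuracy[k]))
  }
})
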