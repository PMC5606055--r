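#' @import methods
NULL

#' CohortTable: a tabular clinical cohort
#'
#' Holds one record per subject: a numeric feature matrix (categorical
#' features coded by 0-based level index), a binary outcome (0 = low risk,
#' 1 = high risk), record identifiers, and per-feature metadata. Feature
#' metadata lives in `featureInfo`, a data.frame with columns `name`, `kind`
#' (one of continuous/binary/ordinal), `nLevels`, `lo`, `hi`, `units` and a
#' `levels` list-column carrying categorical level labels.
#'
#' @slot values numeric matrix, records x features, column names = feature names.
#' @slot outcome integer vector of 0/1 labels, one per record.
#' @slot ids character record identifiers.
#' @slot featureInfo data.frame of per-feature metadata (see above).
#' @slot scaled logical; TRUE after min-max scaling to the unit interval.
#' @slot scalingParams list of per-feature `lo`/`hi` bounds used for scaling
#'   (empty until [scaleFeatures()] is applied).
#'
#' @seealso [loadCohort()], [scaleFeatures()], [splitTrainValidation()]
#' @export
setClass("CohortTable",
  representation(
    values = "matrix",
    outcome = "integer",
    ids = "character",
    featureInfo = "data.frame",
    scaled = "logical",
    scalingParams = "list"
  ),
  prototype(scaled = FALSE, scalingParams = list())
)

setValidity("CohortTable", function(object) {
  msg <- character(0)
  n <- nrow(object@values)
  if (n < 1) msg <- c(msg, "cohort must contain at least one record")
  if (length(object@outcome) != n) msg <- c(msg, "outcome length != record count")
  if (length(object@ids) != n) msg <- c(msg, "ids length != record count")
  if (anyNA(object@values)) msg <- c(msg, "feature matrix contains missing values")
  if (!all(object@outcome %in% c(0L, 1L))) msg <- c(msg, "outcome must be 0/1")
  fi <- object@featureInfo
  if (!identical(colnames(object@values), fi$name))
    msg <- c(msg, "feature matrix columns do not match featureInfo")
  if (!all(fi$kind %in% c("continuous", "binary", "ordinal")))
    msg <- c(msg, "feature kind must be continuous, binary or ordinal")
  if (length(msg)) msg else TRUE
})

#' ExclusionReport: record-exclusion bookkeeping
#'
#' Counts of raw records and of records excluded for missing fields and for
#' age below the eligibility cutoff. Validity enforces the arithmetic
#' identity nFinal = nRaw - nExcludedMissing - nExcludedAge.
#'
#' @slot nRaw,nExcludedMissing,nExcludedAge,nFinal integer counts.
#' @export
setClass("ExclusionReport",
  representation(
    nRaw = "integer",
    nExcludedMissing = "integer",
    nExcludedAge = "integer",
    nFinal = "integer"
  )
)

setValidity("ExclusionReport", function(object) {
  counts <- c(object@nRaw, object@nExcludedMissing, object@nExcludedAge, object@nFinal)
  if (any(counts < 0)) return("all exclusion counts must be nonnegative")
  if (object@nFinal != object@nRaw - object@nExcludedMissing - object@nExcludedAge)
    return("nFinal != nRaw - nExcludedMissing - nExcludedAge")
  TRUE
})

#' NetworkSpec: topology of a masked single-hidden-layer network
#'
#' The mask is an nInput x nHidden binary matrix; entry (i, h) = 1 means
#' input i connects to hidden unit h. All hidden units connect to the single
#' output. Validity requires every hidden unit to receive at least one input
#' and every input to reach at least one hidden unit.
#'
#' @slot nInput,nHidden integer node counts.
#' @slot mask binary matrix, nInput x nHidden.
#' @slot activation name of the sigmoidal nonlinearity ("logistic").
#' @slot featureNames character names of the input features.
#' @export
setClass("NetworkSpec",
  representation(
    nInput = "integer",
    nHidden = "integer",
    mask = "matrix",
    activation = "character",
    featureNames = "character"
  )
)

setValidity("NetworkSpec", function(object) {
  msg <- character(0)
  if (object@nInput < 1L || object@nHidden < 1L)
    msg <- c(msg, "need at least one input and one hidden unit")
  if (!identical(dim(object@mask), c(object@nInput, object@nHidden)))
    msg <- c(msg, "mask dimensions must be nInput x nHidden")
  if (!all(object@mask %in% c(0, 1)))
    msg <- c(msg, "mask entries must be 0 or 1")
  else {
    if (any(colSums(object@mask) < 1))
      msg <- c(msg, "every hidden unit needs at least one incoming connection")
    if (any(rowSums(object@mask) < 1))
      msg <- c(msg, "every input must reach the output through some hidden unit")
  }
  if (!identical(object@activation, "logistic"))
    msg <- c(msg, "only the logistic activation is supported")
  if (length(object@featureNames) != object@nInput)
    msg <- c(msg, "featureNames length must equal nInput")
  if (length(msg)) msg else TRUE
})

#' TrainedNetwork: weights of a (possibly masked) single-hidden-layer network
#'
#' Input-to-hidden weights are exactly zero wherever the spec's mask is zero;
#' this holds before, during and after training (gradients at masked
#' positions are forced to zero rather than re-projected).
#'
#' @slot spec a [NetworkSpec-class].
#' @slot W numeric matrix of input-to-hidden weights (nInput x nHidden).
#' @slot bHidden numeric hidden biases.
#' @slot wOut numeric hidden-to-output weights.
#' @slot bOut numeric output bias (length 1).
#' @slot config list echo of the training configuration.
#' @slot lossHistory numeric per-epoch training loss (empty before training).
#' @export
setClass("TrainedNetwork",
  representation(
    spec = "NetworkSpec",
    W = "matrix",
    bHidden = "numeric",
    wOut = "numeric",
    bOut = "numeric",
    config = "list",
    lossHistory = "numeric"
  ),
  prototype(lossHistory = numeric(0))
)

setValidity("TrainedNetwork", function(object) {
  msg <- character(0)
  sp <- object@spec
  if (!identical(dim(object@W), c(sp@nInput, sp@nHidden)))
    msg <- c(msg, "weight matrix dimensions do not match spec")
  if (length(object@bHidden) != sp@nHidden) msg <- c(msg, "bHidden length != nHidden")
  if (length(object@wOut) != sp@nHidden) msg <- c(msg, "wOut length != nHidden")
  if (length(object@bOut) != 1L) msg <- c(msg, "bOut must have length 1")
  if (identical(dim(object@W), c(sp@nInput, sp@nHidden)) &&
      any(object@W[sp@mask == 0] != 0))
    msg <- c(msg, "masked weights must be exactly zero")
  if (length(msg)) msg else TRUE
})

#' SensitivityProfile: per-feature perturbation sensitivities with ranks
#'
#' Sensitivity of feature i is the mean absolute change in the network output
#' across all records when feature i is shifted by a small delta. Rank 1 is
#' the largest sensitivity; ties break by original feature order.
#'
#' @slot featureNames character.
#' @slot sen numeric nonnegative sensitivities.
#' @slot rank integer 1-based ranks, a permutation of 1..F.
#' @export
setClass("SensitivityProfile",
  representation(
    featureNames = "character",
    sen = "numeric",
    rank = "integer"
  )
)

setValidity("SensitivityProfile", function(object) {
  msg <- character(0)
  f <- length(object@featureNames)
  if (length(object@sen) != f || length(object@rank) != f)
    msg <- c(msg, "sen and rank must match featureNames in length")
  if (any(object@sen < 0)) msg <- c(msg, "sensitivities must be nonnegative")
  if (!setequal(object@rank, seq_len(f))) msg <- c(msg, "ranks must be a permutation of 1..F")
  if (length(msg) == 0 && f > 1) {
    ord <- order(object@rank)
    if (is.unsorted(-object@sen[ord]) && any(diff(object@sen[ord]) > 0))
      msg <- c(msg, "ranks must be consistent with descending sensitivity")
  }
  if (length(msg)) msg else TRUE
})

#' EliminationTrace: the stepwise feature-elimination accuracy curve
#'
#' Stage k corresponds to the cumulative removal of the first k features in
#' `removed`, with the network retrained on the remainder; `accuracy[k]` is
#' the validation accuracy (percent) at that stage. `baselineAccuracy` is the
#' all-features accuracy (may be NA for replayed curves that do not print it).
#'
#' @slot featureNames full feature set the trace started from (may be empty
#'   for replayed curves with unknown context).
#' @slot removed character, features in removal order.
#' @slot accuracy numeric percentages, one per stage.
#' @slot baselineAccuracy numeric length 1.
#' @export
setClass("EliminationTrace",
  representation(
    featureNames = "character",
    removed = "character",
    accuracy = "numeric",
    baselineAccuracy = "numeric"
  ),
  prototype(featureNames = character(0), baselineAccuracy = NA_real_)
)

setValidity("EliminationTrace", function(object) {
  msg <- character(0)
  if (length(object@removed) != length(object@accuracy))
    msg <- c(msg, "one accuracy per removal stage required")
  if (anyDuplicated(object@removed))
    msg <- c(msg, "a feature cannot be removed twice (removed sets are nested)")
  if (length(object@featureNames) &&
      !all(object@removed %in% object@featureNames))
    msg <- c(msg, "removed features must belong to featureNames")
  if (length(object@baselineAccuracy) != 1L)
    msg <- c(msg, "baselineAccuracy must have length 1")
  if (length(msg)) msg else TRUE
})

#' SensitivityChangeMatrix: sensitivity changes under single-feature amplification
#'
#' Cell (i, j) is the absolute change in feature i's sensitivity when feature
#' j is amplified by a small delta across the whole dataset. `columnMeans[j]`
#' is the average of column j over all rows including the diagonal; when a
#' matrix is read from a file that carries its own average row, those stored
#' averages are kept as authoritative (they may differ from the recomputed
#' means by up to 1e-3 due to rounding of published 3-decimal tables).
#'
#' @slot featureNames character, length F.
#' @slot cells numeric F x F matrix, rows = measured feature, columns =
#'   amplified feature.
#' @slot columnMeans numeric length F.
#' @export
setClass("SensitivityChangeMatrix",
  representation(
    featureNames = "character",
    cells = "matrix",
    columnMeans = "numeric"
  )
)

setValidity("SensitivityChangeMatrix", function(object) {
  msg <- character(0)
  f <- length(object@featureNames)
  if (!identical(dim(object@cells), c(f, f)))
    msg <- c(msg, "cells must be F x F")
  else {
    if (any(object@cells < 0)) msg <- c(msg, "cells must be nonnegative")
    if (length(object@columnMeans) != f)
      msg <- c(msg, "columnMeans length must equal F")
    else if (any(abs(object@columnMeans - colMeans(object@cells)) > 1e-3))
      msg <- c(msg, "columnMeans inconsistent with cells (tolerance 1e-3)")
  }
  if (length(msg)) msg else TRUE
})

#' CorrelationGraph: mutually-detected feature correlations
#'
#' An unordered pair {i, j} is present iff i is a candidate under
#' amplification of j AND j is a candidate under amplification of i.
#' `groups` partitions the feature set into the connected components of the
#' pair graph; features in no pair form singleton groups.
#'
#' @slot featureNames character.
#' @slot pairs character matrix with two columns, one row per unordered pair.
#' @slot groups list of character vectors partitioning featureNames.
#' @export
setClass("CorrelationGraph",
  representation(
    featureNames = "character",
    pairs = "matrix",
    groups = "list"
  )
)

setValidity("CorrelationGraph", function(object) {
  msg <- character(0)
  if (ncol(object@pairs) != 2 && nrow(object@pairs) > 0)
    msg <- c(msg, "pairs must have two columns")
  if (nrow(object@pairs) > 0 && !all(object@pairs %in% object@featureNames))
    msg <- c(msg, "pair members must be features")
  allg <- unlist(object@groups)
  if (!setequal(allg, object@featureNames) || anyDuplicated(allg))
    msg <- c(msg, "groups must partition the feature set")
  if (nrow(object@pairs) > 0 && length(msg) == 0) {
    gid <- rep(seq_along(object@groups), lengths(object@groups))
    names(gid) <- allg
    if (any(gid[object@pairs[, 1]] != gid[object@pairs[, 2]]))
      msg <- c(msg, "both members of a pair must share a group")
  }
  if (length(msg)) msg else TRUE
})

#' MetricsReport: confusion-matrix metrics and ROC AUC
#'
#' PPV, NPV and accuracy are percentages; AUC is on [0, 1] with an optional
#' 95 percent bootstrap confidence interval. PPV (NPV) is NA with an entry in
#' `flags` when no record is predicted positive (negative).
#'
#' @slot tp,fp,fn,tn integer confusion counts.
#' @slot ppv,npv,accuracy numeric percentages (NA when undefined).
#' @slot auc numeric in [0, 1] (NA when not computed).
#' @slot aucCi numeric length 2, lower and upper bound (NA when not computed).
#' @slot flags character notes (e.g. "ppv_undefined", "separation").
#' @export
setClass("MetricsReport",
  representation(
    tp = "integer", fp = "integer", fn = "integer", tn = "integer",
    ppv = "numeric", npv = "numeric", accuracy = "numeric",
    auc = "numeric", aucCi = "numeric", flags = "character"
  ),
  prototype(auc = NA_real_, aucCi = c(NA_real_, NA_real_), flags = character(0))
)

setValidity("MetricsReport", function(object) {
  msg <- character(0)
  counts <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(counts < 0)) msg <- c(msg, "confusion counts must be nonnegative")
  for (nm in c("ppv", "npv", "accuracy")) {
    v <- slot(object, nm)
    if (!is.na(v) && (v < 0 || v > 100)) msg <- c(msg, paste(nm, "must be in [0, 100]"))
  }
  if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1))
    msg <- c(msg, "auc must be in [0, 1]")
  if (length(object@aucCi) != 2L) msg <- c(msg, "aucCi must have length 2")
  if (length(msg)) msg else TRUE
})

#' PipelineReport: results of the full risk-prediction workflow
#'
#' Bundles every stage output: exclusion bookkeeping (when the cohort came
#' from a file), the all-features sensitivity profile, the elimination trace
#' and selected feature subset, the sensitivity-change matrix and correlation
#' graph on the selected features, the structured-network spec, and metrics
#' for the logistic-regression, dense-network and structured-network models
#' on a shared validation split.
#'
#' @slot exclusion an [ExclusionReport-class] or NULL.
#' @slot profile a [SensitivityProfile-class].
#' @slot trace an [EliminationTrace-class].
#' @slot selectedFeatures character.
#' @slot changeMatrix a [SensitivityChangeMatrix-class].
#' @slot graph a [CorrelationGraph-class].
#' @slot structuredSpec the coupled-connection [NetworkSpec-class].
#' @slot metrics named list of validation-split [MetricsReport-class]
#'   objects (lr, nn, nnfca).
#' @slot trainingMetrics the same three models evaluated on the training
#'   split (no confidence intervals).
#' @slot truth ground-truth list for simulated cohorts, or NULL.
#' @slot seeds named list of the seeds that drove each stochastic stage.
#' @export
setClass("PipelineReport",
  representation(
    exclusion = "ANY",
    profile = "SensitivityProfile",
    trace = "EliminationTrace",
    selectedFeatures = "character",
    changeMatrix = "SensitivityChangeMatrix",
    graph = "CorrelationGraph",
    structuredSpec = "NetworkSpec",
    metrics = "list",
    trainingMetrics = "list",
    truth = "ANY",
    seeds = "list"
  )
)
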