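#' Perturbation settings for the sensitivity analysis
#'
#' The perturbation delta is drawn uniformly from [deltaMin, deltaMax] in
#' scaled-feature units. Each feature's draw is seeded independently
#' (seed + feature index), so a single feature's sensitivity is identical
#' whether computed alone or as part of a profile, and independent of the
#' order of computation.
#'
#' @param deltaMin,deltaMax positive bounds of the uniform delta draw,
#'   0 < deltaMin <= deltaMax; defaults 1e-4 and 1e-3.
#' @param seed integer base seed.
#' @param perRecord draw one delta per record instead of one shared delta per
#'   feature evaluation.
#' @return a validated perturbation-spec list.
#' @export
perturbationSpec <- function(deltaMin = 1e-4, deltaMax = 1e-3, seed = 1L,
                             perRecord = FALSE) {
  if (deltaMin <= 0) stop("deltaMin must be positive")
  if (deltaMin > deltaMax) stop("deltaMin must be <= deltaMax")
  structure(list(deltaMin = deltaMin, deltaMax = deltaMax,
                 seed = as.integer(seed), perRecord = isTRUE(perRecord)),
            class = "nnfca_perturbationSpec")
}

.drawDelta <- function(pert, featureIndex, n = 1) {
  withr::with_seed(pert$seed + featureIndex,
                   stats::runif(n, pert$deltaMin, pert$deltaMax))
}

#' Shift one feature column by a fixed delta
#'
#' Returns a copy of the table with `delta` added to every record's value of
#' `feature`; the input table is not modified.
#'
#' @param table a [CohortTable-class].
#' @param feature feature name.
#' @param delta shift (scaled-feature units).
#' @return the perturbed [CohortTable-class].
#' @export
perturbFeature <- function(table, feature, delta) {
  stopifnot(is(table, "CohortTable"))
  k <- match(feature, colnames(table@values))
  if (is.na(k)) stop("unknown feature: ", feature)
  v <- table@values
  v[, k] <- v[, k] + delta
  initialize(table, values = v)
}

# Core: sensitivity of one feature for a given delta (scalar or per-record).
.sensitivityWithDelta <- function(net, table, featureIndex, delta) {
  X <- table@values
  p0 <- forward(net, X)
  Xp <- X
  Xp[, featureIndex] <- Xp[, featureIndex] + delta
  mean(abs(forward(net, Xp) - p0))
}

#' Perturbation sensitivity of a single feature
#'
#' Sen(X, x_i) = (1/N) sum_k | NNoutput_k(X with x_i + delta) - NNoutput_k(X) |,
#' the mean absolute change of the trained network's output over all records
#' when feature i is shifted by a small delta. Absolute differences are used
#' so record-level changes cannot cancel. Deterministic given the
#' perturbation seed.
#'
#' @param net a [TrainedNetwork-class] trained on the table's feature order.
#' @param table a scaled [CohortTable-class].
#' @param feature feature name.
#' @param pert a [perturbationSpec()].
#' @param delta optionally force a specific delta (bypasses the seeded draw);
#'   used by the amplification analysis.
#' @return nonnegative sensitivity value (at most 1, the output range).
#' @export
featureSensitivity <- function(net, table, feature, pert = perturbationSpec(),
                               delta = NULL) {
  k <- match(feature, colnames(table@values))
  if (is.na(k)) stop("unknown feature: ", feature)
  if (is.null(delta))
    delta <- .drawDelta(pert, k, if (pert$perRecord) nrow(table@values) else 1)
  .sensitivityWithDelta(net, table, k, delta)
}

#' Rank features by descending sensitivity
#'
#' Rank 1 is the largest value; ties break by original feature order (stable).
#'
#' @param sen numeric vector of finite sensitivity values.
#' @return integer ranks, a permutation of 1..length(sen).
#' @export
rankFeatures <- function(sen) {
  if (!all(is.finite(sen))) stop("sensitivities must be finite")
  ord <- order(-sen, seq_along(sen))
  r <- integer(length(sen))
  r[ord] <- seq_along(sen)
  r
}

#' Sensitivity profile of every feature
#'
#' Each feature's sensitivity is computed individually (its own seeded delta
#' draw, all other features untouched); ranks are assigned by
#' [rankFeatures()].
#'
#' @param net a [TrainedNetwork-class].
#' @param table a scaled [CohortTable-class].
#' @param pert a [perturbationSpec()].
#' @return a [SensitivityProfile-class].
#' @export
sensitivityProfile <- function(net, table, pert = perturbationSpec()) {
  fn <- colnames(table@values)
  sen <- vapply(fn, function(f) featureSensitivity(net, table, f, pert), 0)
  new("SensitivityProfile", featureNames = fn, sen = unname(sen),
      rank = rankFeatures(unname(sen)))
}

#' Write a sensitivity profile as CSV (feature, sensitivity, rank)
#' @param profile a [SensitivityProfile-class].
#' @param path output path.
#' @export
writeSensitivityCsv <- function(profile, path) {
  utils::write.csv(data.frame(feature = profile@featureNames,
                              sensitivity = profile@sen, rank = profile@rank),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a sensitivity profile to JSON
#' @param profile a [SensitivityProfile-class].
#' @param path optional file path; when NULL the JSON string is returned.
#' @export
writeSensitivityJson <- function(profile, path = NULL) {
  x <- list(feature = profile@featureNames, sensitivity = profile@sen,
            rank = profile@rank)
  if (is.null(path)) return(jsonlite::toJSON(x, digits = NA))
  jsonlite::write_json(x, path, digits = NA)
  invisible(path)
}

#' @describeIn SensitivityProfile sensitivity values in feature order
#' @param x a SensitivityProfile
#' @export
setMethod("sensitivities", "SensitivityProfile", function(x) {
  stats::setNames(x@sen, x@featureNames)
})

#' @describeIn SensitivityProfile 1-based ranks (1 = most sensitive)
#' @export
setMethod("featureRanks", "SensitivityProfile", function(x) {
  stats::setNames(x@rank, x@featureNames)
})

#' @describeIn SensitivityProfile feature names
#' @export
setMethod("featureNames", "SensitivityProfile", function(x) x@featureNames)

setMethod("show", "SensitivityProfile", function(object) {
  ord <- order(object@rank)
  cat("SensitivityProfile (", length(object@featureNames), " features)\n", sep = "")
  top <- utils::head(ord, 5)
  for (k in top)
    cat(sprintf("  %2d. %-14s %.4g\n", object@rank[k],
                object@featureNames[k], object@sen[k]))
  if (length(ord) > 5) cat("  ...\n")
})
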