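#' Confusion-matrix metrics at a classification threshold
#'
#' Prediction is positive iff score >= threshold. PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN), accuracy = (TP+TN)/N, each expressed as a percentage.
#' When no record is predicted positive (negative), PPV (NPV) is NA and a
#' flag is recorded.
#'
#' @param labels 0/1 vector.
#' @param scores probabilities aligned with labels.
#' @param threshold cutoff in (0, 1).
#' @return a [MetricsReport-class] (AUC slots left NA; see [rocAuc()]).
#' @export
confusionMetrics <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) stop("labels and scores must align")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  pred <- scores >= threshold
  pos <- labels == 1
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  flags <- character(0)
  ppv <- if (tp + fp == 0) { flags <- c(flags, "ppv_undefined"); NA_real_ }
         else 100 * tp / (tp + fp)
  npv <- if (tn + fn == 0) { flags <- c(flags, "npv_undefined"); NA_real_ }
         else 100 * tn / (tn + fn)
  new("MetricsReport", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn),
      ppv = ppv, npv = npv,
      accuracy = 100 * (tp + tn) / length(labels), flags = flags)
}

#' ROC area under the curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a uniformly chosen
#' positive record outscores a uniformly chosen negative one, ties counted
#' one half. Equals the trapezoidal area under the empirical ROC curve and is
#' invariant under strictly monotone transformations of the scores.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores probabilities (or any monotone score).
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(labels, scores) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties with half credit
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap confidence interval for the AUC
#'
#' 95 percent percentile interval over class-stratified resamples of the
#' records (stratification keeps both classes in every resample). Seeded and
#' reproducible.
#'
#' @param labels 0/1 vector.
#' @param scores aligned probabilities.
#' @param nBoot number of resamples (>= 100).
#' @param seed integer seed.
#' @return numeric c(lower, upper).
#' @export
aucCi <- function(labels, scores, nBoot = 1000L, seed = 1L) {
  if (nBoot < 100) stop("nBoot must be >= 100")
  idxPos <- which(labels == 1)
  idxNeg <- which(labels == 0)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(nBoot), function(b) {
      i <- c(sample(idxPos, length(idxPos), replace = TRUE),
             sample(idxNeg, length(idxNeg), replace = TRUE))
      rocAuc(labels[i], scores[i])
    }, 0)
  })
  unname(stats::quantile(boots, c(0.025, 0.975)))
}

#' Evaluate a trained network on a cohort
#'
#' Convenience wrapper: confusion metrics at the threshold plus AUC and,
#' when `nBoot > 0`, its bootstrap confidence interval.
#'
#' @param net a [TrainedNetwork-class].
#' @param table a [CohortTable-class] on the model's feature set.
#' @param threshold classification cutoff.
#' @param nBoot bootstrap resamples for the AUC CI (0 skips the CI).
#' @param seed bootstrap seed.
#' @return a [MetricsReport-class].
#' @export
evaluateNetwork <- function(net, table, threshold = 0.5, nBoot = 0L, seed = 1L) {
  scores <- forward(net, table)
  .scoreReport(table@outcome, scores, threshold, nBoot, seed)
}

.scoreReport <- function(labels, scores, threshold, nBoot, seed,
                         extraFlags = character(0)) {
  rep <- confusionMetrics(labels, scores, threshold)
  auc <- rocAuc(labels, scores)
  ci <- if (nBoot > 0) aucCi(labels, scores, nBoot, seed) else c(NA_real_, NA_real_)
  initialize(rep, auc = auc, aucCi = ci, flags = c(rep@flags, extraFlags))
}

#' Logistic-regression comparator
#'
#' Maximum-likelihood logistic model on the training features, evaluated on
#' the validation split. Serves only as a baseline for the network models. A
#' "separation" flag is raised when the fit reports fitted probabilities of
#' 0 or 1 (perfectly separable data).
#'
#' @param train,validate [CohortTable-class] pairs on the same features.
#' @param threshold classification cutoff.
#' @param nBoot bootstrap resamples for the AUC CI (0 skips it).
#' @param seed bootstrap seed.
#' @return list with `report` (a [MetricsReport-class]) and `coefficients`
#'   (named vector including the intercept).
#' @export
fitLogisticBaseline <- function(train, validate, threshold = 0.5,
                                nBoot = 0L, seed = 1L) {
  df <- data.frame(train@values, y = train@outcome, check.names = FALSE)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  newdf <- data.frame(validate@values, check.names = FALSE)
  scores <- stats::predict(fit, newdata = newdf, type = "response")
  report <- .scoreReport(validate@outcome, scores, threshold, nBoot, seed,
                         if (separated) "separation" else character(0))
  list(report = report, coefficients = stats::coef(fit))
}

#' Render a comparison table of model metrics
#'
#' One row per model with PPV, NPV, accuracy (percent) and AUC with its CI,
#' mirroring the usual clinical-comparison layout.
#'
#' @param reports named list of [MetricsReport-class] objects.
#' @return a data.frame (printed with [print()]).
#' @export
metricsTable <- function(reports) {
  data.frame(
    model = names(reports),
    PPV = vapply(reports, function(r) r@ppv, 0),
    NPV = vapply(reports, function(r) r@npv, 0),
    Accuracy = vapply(reports, function(r) r@accuracy, 0),
    AUC = vapply(reports, function(r) r@auc, 0),
    AUC_lower = vapply(reports, function(r) r@aucCi[1], 0),
    AUC_upper = vapply(reports, function(r) r@aucCi[2], 0),
    row.names = NULL
  )
}

#' Serialize a metrics report to JSON
#' @param report a [MetricsReport-class].
#' @param path optional file path; when NULL the JSON string is returned.
#' @export
writeMetricsJson <- function(report, path = NULL) {
  x <- list(tp = report@tp, fp = report@fp, fn = report@fn, tn = report@tn,
            ppv = report@ppv, npv = report@npv, accuracy = report@accuracy,
            auc = report@auc, auc_ci = report@aucCi, flags = report@flags)
  if (is.null(path)) return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @describeIn MetricsReport named confusion counts (tp, fp, fn, tn)
#' @param x a MetricsReport
#' @export
setMethod("confusionCounts", "MetricsReport", function(x) {
  c(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn)
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: PPV %.2f%%, NPV %.2f%%, accuracy %.2f%%",
              object@ppv, object@npv, object@accuracy))
  if (!is.na(object@auc)) {
    cat(sprintf(", AUC %.3f", object@auc))
    if (!anyNA(object@aucCi))
      cat(sprintf(" [%.3f, %.3f]", object@aucCi[1], object@aucCi[2]))
  }
  cat("\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})
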