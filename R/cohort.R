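#' Describe one cohort feature
#'
#' @param name feature name as it appears in the CSV header.
#' @param kind "continuous", "binary" or "ordinal".
#' @param levels ordered character levels (categorical kinds only; at least 2).
#' @param validRange inclusive numeric bounds c(lo, hi) (continuous only).
#' @param units free-text units.
#' @return a feature-spec list consumed by [loadCohort()].
#' @export
featureSpec <- function(name, kind = c("continuous", "binary", "ordinal"),
                        levels = NULL, validRange = NULL, units = "") {
  kind <- match.arg(kind)
  if (kind == "continuous") {
    if (is.null(validRange)) validRange <- c(-Inf, Inf)
    if (length(validRange) != 2 || validRange[1] >= validRange[2])
      stop("validRange must be c(lo, hi) with lo < hi")
    levels <- character(0)
  } else {
    if (is.null(levels) || length(levels) < 2)
      stop("categorical features need at least 2 ordered levels")
    if (kind == "binary" && length(levels) != 2)
      stop("binary features need exactly 2 levels")
    validRange <- c(NA_real_, NA_real_)
  }
  list(name = name, kind = kind, levels = as.character(levels),
       validRange = as.numeric(validRange), units = units)
}

#' Default feature set for a health-survey CHD cohort
#'
#' The sixteen clinical features of the coronary-heart-disease risk problem:
#' eight continuous measurements, seven binary conditions and a three-level
#' ordinal diabetes status (no / impaired fasting glucose / diabetes).
#'
#' @return list of feature specs (see [featureSpec()]).
#' @export
defaultFeatureSpecs <- function() {
  yn <- c("no", "yes")
  list(
    featureSpec("age", "continuous", validRange = c(0, 120), units = "years"),
    featureSpec("sex", "binary", levels = c("male", "female")),
    featureSpec("BMI", "continuous", validRange = c(10, 60), units = "kg/m^2"),
    featureSpec("To_chole", "continuous", validRange = c(50, 600), units = "mg/dL"),
    featureSpec("HDL", "continuous", validRange = c(10, 200), units = "mg/dL"),
    featureSpec("SBP", "continuous", validRange = c(50, 250), units = "mmHg"),
    featureSpec("DBP", "continuous", validRange = c(10, 160), units = "mmHg"),
    featureSpec("triglyceride", "continuous", validRange = c(10, 2000), units = "mg/dL"),
    featureSpec("hemoglobin", "continuous", validRange = c(4, 25), units = "g/dL"),
    featureSpec("TD", "binary", levels = yn),
    featureSpec("CRF", "binary", levels = yn),
    featureSpec("H_B", "binary", levels = yn),
    featureSpec("H_C", "binary", levels = yn),
    featureSpec("cirrhosis", "binary", levels = yn),
    featureSpec("smoking", "binary", levels = yn),
    featureSpec("diabetes", "ordinal",
                levels = c("no", "impaired_fasting_glucose", "diabetes"))
  )
}

#' The five component-disease columns that define high CHD risk
#' @export
componentDiseaseColumns <- function() {
  c("hypertension", "dyslipidemia", "stroke", "myocardial_infarction", "angina")
}

.specsToFeatureInfo <- function(specs) {
  fi <- data.frame(
    name = vapply(specs, `[[`, "", "name"),
    kind = vapply(specs, `[[`, "", "kind"),
    nLevels = vapply(specs, function(s) length(s$levels), 0L),
    lo = vapply(specs, function(s) s$validRange[1], 0),
    hi = vapply(specs, function(s) s$validRange[2], 0),
    units = vapply(specs, `[[`, "", "units"),
    stringsAsFactors = FALSE
  )
  fi$levels <- lapply(specs, `[[`, "levels")
  fi
}

#' Construct a CohortTable from in-memory data
#'
#' @param values numeric matrix (records x features); categoricals coded by
#'   0-based level index.
#' @param outcome 0/1 vector.
#' @param specs list of [featureSpec()]s matching the columns of `values`.
#' @param ids record identifiers (defaults to row numbers).
#' @return a [CohortTable-class].
#' @export
cohortTable <- function(values, outcome, specs, ids = NULL) {
  values <- as.matrix(values)
  fi <- .specsToFeatureInfo(specs)
  colnames(values) <- fi$name
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  new("CohortTable", values = values, outcome = as.integer(outcome),
      ids = as.character(ids), featureInfo = fi)
}

#' Derive the binary CHD-risk outcome from component-disease flags
#'
#' A subject is labelled high risk (1) iff at least one of the five component
#' conditions (hypertension, dyslipidemia, stroke, myocardial infarction,
#' angina) is present.
#'
#' @param componentFlags N x 5 matrix or data.frame of 0/1 flags.
#' @return integer vector of 0/1 labels.
#' @export
deriveOutcome <- function(componentFlags) {
  m <- as.matrix(componentFlags)
  storage.mode(m) <- "numeric"
  if (anyNA(m) || !all(m %in% c(0, 1)))
    stop("component-disease flags must be 0/1 with no missing values")
  as.integer(rowSums(m) > 0)
}

.isMissingToken <- function(x) is.na(x) | x == "" | x == "Null"

#' Load, validate and filter a cohort CSV
#'
#' Reads a UTF-8 CSV with a header row, one record per line; missing values
#' are empty cells or the literal "Null". Records with any missing field
#' among the spec'd features and outcome columns are excluded first; among
#' the remainder, records with age below `minAge` are excluded (each record
#' is counted once, in the first rule it violates). The outcome is taken from
#' `outcomeColumn` when present, otherwise derived from the five
#' component-disease columns via [deriveOutcome()].
#'
#' @param path CSV file path.
#' @param specs feature specs; default [defaultFeatureSpecs()].
#' @param outcomeColumn name of the 0/1 outcome column.
#' @param componentColumns names of the five component-disease flag columns.
#' @param ageFeature name of the age feature used for the age rule (set to
#'   NULL to skip the age exclusion).
#' @param minAge eligibility cutoff in years.
#' @return list with elements `table` (a [CohortTable-class]) and
#'   `exclusion` (an [ExclusionReport-class]).
#' @export
loadCohort <- function(path, specs = defaultFeatureSpecs(),
                       outcomeColumn = "chd_risk",
                       componentColumns = componentDiseaseColumns(),
                       ageFeature = "age", minAge = 30) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(0))
  fi <- .specsToFeatureInfo(specs)
  missingCols <- setdiff(fi$name, colnames(raw))
  if (length(missingCols))
    stop("schema error: spec'd feature(s) not in CSV header: ",
         paste(missingCols, collapse = ", "))
  if (outcomeColumn %in% colnames(raw)) {
    outcomeCols <- outcomeColumn
    useComponents <- FALSE
  } else if (all(componentColumns %in% colnames(raw))) {
    outcomeCols <- componentColumns
    useComponents <- TRUE
  } else {
    stop("schema error: need an outcome column ('", outcomeColumn,
         "') or the five component-disease columns")
  }

  nRaw <- nrow(raw)
  relevant <- raw[, c(fi$name, outcomeCols), drop = FALSE]
  missingRow <- Reduce(`|`, lapply(relevant, .isMissingToken))
  kept <- raw[!missingRow, , drop = FALSE]
  nMissing <- sum(missingRow)

  nAge <- 0L
  if (!is.null(ageFeature) && ageFeature %in% fi$name) {
    age <- suppressWarnings(as.numeric(kept[[ageFeature]]))
    young <- !is.na(age) & age < minAge
    nAge <- sum(young)
    kept <- kept[!young, , drop = FALSE]
  }
  nFinal <- nrow(kept)
  if (nFinal == 0)
    stop("degenerate input: no records remain after exclusions")

  values <- matrix(NA_real_, nFinal, nrow(fi), dimnames = list(NULL, fi$name))
  for (k in seq_len(nrow(fi))) {
    col <- kept[[fi$name[k]]]
    if (fi$kind[k] == "continuous") {
      v <- suppressWarnings(as.numeric(col))
      if (anyNA(v))
        stop("validation error: non-numeric value in continuous feature '",
             fi$name[k], "'")
      nOut <- sum(v < fi$lo[k] | v > fi$hi[k])
      if (nOut > 0)
        warning(nOut, " value(s) of '", fi$name[k], "' outside valid range [",
                fi$lo[k], ", ", fi$hi[k], "]")
      values[, k] <- v
    } else {
      levs <- fi$levels[[k]]
      idx <- match(col, levs)
      if (anyNA(idx)) {
        # numeric coding (0-based level index) is also accepted
        vnum <- suppressWarnings(as.numeric(col))
        if (!anyNA(vnum) && all(vnum %in% (seq_along(levs) - 1))) {
          idx <- vnum + 1
        } else {
          stop("validation error: unknown level in feature '", fi$name[k], "'")
        }
      }
      values[, k] <- idx - 1
    }
  }

  if (useComponents) {
    flags <- vapply(kept[, componentColumns, drop = FALSE],
                    function(x) suppressWarnings(as.numeric(x)),
                    numeric(nFinal))
    y <- deriveOutcome(matrix(flags, nrow = nFinal))
  } else {
    y <- suppressWarnings(as.numeric(kept[[outcomeColumn]]))
    if (anyNA(y) || !all(y %in% c(0, 1)))
      stop("validation error: outcome column must be 0/1")
    y <- as.integer(y)
  }

  ids <- if ("id" %in% colnames(kept)) as.character(kept[["id"]])
         else as.character(seq_len(nFinal))
  table <- new("CohortTable", values = values, outcome = y, ids = ids,
               featureInfo = fi)
  exclusion <- new("ExclusionReport", nRaw = as.integer(nRaw),
                   nExcludedMissing = as.integer(nMissing),
                   nExcludedAge = as.integer(nAge),
                   nFinal = as.integer(nFinal))
  list(table = table, exclusion = exclusion)
}

#' Min-max scale a cohort to the unit interval
#'
#' Continuous features are scaled by (x - lo) / (hi - lo); categorical
#' features become level index / (nLevels - 1), so a two-level feature maps
#' to {0, 1} and the three-level diabetes status to {0, 0.5, 1}. A common
#' scale is required because the perturbation magnitude used by the
#' sensitivity analysis is a single small number applied to any feature.
#'
#' When `params` is NULL the bounds are the observed column ranges (use the
#' training split's params to scale a validation split). A constant feature
#' is scaled to 0 with a warning. Re-applying with the identical params to an
#' already-scaled table is a no-op.
#'
#' @param table a [CohortTable-class].
#' @param params scaling parameters from a previous call, or NULL.
#' @return the scaled [CohortTable-class]; retrieve the parameters with
#'   [scalingParams()].
#' @export
scaleFeatures <- function(table, params = NULL) {
  stopifnot(is(table, "CohortTable"))
  if (isScaled(table)) {
    if (is.null(params) || identical(params, table@scalingParams))
      return(table)
    stop("table is already scaled with different parameters")
  }
  fi <- table@featureInfo
  v <- table@values
  if (is.null(params)) {
    params <- lapply(seq_len(nrow(fi)), function(k) {
      if (fi$kind[k] == "continuous") {
        lo <- min(v[, k]); hi <- max(v[, k])
      } else {
        lo <- 0; hi <- fi$nLevels[k] - 1
      }
      list(lo = lo, hi = hi, constant = hi == lo)
    })
    names(params) <- fi$name
  }
  for (k in seq_len(nrow(fi))) {
    p <- params[[fi$name[k]]]
    if (isTRUE(p$constant)) {
      warning("feature '", fi$name[k], "' is constant; scaled to 0")
      v[, k] <- 0
    } else {
      v[, k] <- (v[, k] - p$lo) / (p$hi - p$lo)
    }
  }
  initialize(table, values = v, scaled = TRUE, scalingParams = params)
}

#' Stratified train/validation split
#'
#' Splits by outcome class so both partitions keep the class mix; disjoint
#' and exhaustive, reproducible for a given seed.
#'
#' @param table a [CohortTable-class].
#' @param fraction training fraction in (0, 1).
#' @param seed integer RNG seed.
#' @return list with [CohortTable-class] elements `train` and `validation`.
#' @export
splitTrainValidation <- function(table, fraction = 0.7, seed = 20170906L) {
  stopifnot(is(table, "CohortTable"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  y <- table@outcome
  trainIdx <- withr::with_seed(seed, {
    unlist(lapply(unique(y), function(cls) {
      idx <- which(y == cls)
      sample(idx, round(fraction * length(idx)))
    }))
  })
  trainIdx <- sort(trainIdx)
  list(train = table[trainIdx, ],
       validation = table[setdiff(seq_along(y), trainIdx), ])
}

#' Write a cohort back to CSV (current coding/scaling)
#' @param table a [CohortTable-class].
#' @param path output path.
#' @export
writeCohortCsv <- function(table, path) {
  df <- data.frame(id = table@ids, table@values, chd_risk = table@outcome,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an exclusion report to JSON
#' @param report an [ExclusionReport-class].
#' @param path optional file path; when NULL the JSON string is returned.
#' @export
writeExclusionJson <- function(report, path = NULL) {
  x <- list(n_raw = report@nRaw, n_excluded_missing = report@nExcludedMissing,
            n_excluded_age = report@nExcludedAge, n_final = report@nFinal)
  if (is.null(path)) return(jsonlite::toJSON(x, auto_unbox = TRUE))
  jsonlite::write_json(x, path, auto_unbox = TRUE)
  invisible(path)
}

# ---- accessors & methods ----------------------------------------------------

#' @describeIn CohortTable number of records
#' @param x a CohortTable
#' @export
setMethod("nRecords", "CohortTable", function(x) nrow(x@values))

#' @describeIn CohortTable feature names
#' @export
setMethod("featureNames", "CohortTable", function(x) colnames(x@values))

#' @describeIn CohortTable the numeric feature matrix
#' @export
setMethod("featureMatrix", "CohortTable", function(x) x@values)

#' @describeIn CohortTable the 0/1 outcome vector
#' @export
setMethod("outcome", "CohortTable", function(x) x@outcome)

#' @describeIn CohortTable per-feature metadata data.frame
#' @export
setMethod("featureInfo", "CohortTable", function(x) x@featureInfo)

#' @describeIn CohortTable TRUE once min-max scaled
#' @export
setMethod("isScaled", "CohortTable", function(x) x@scaled)

#' @describeIn CohortTable scaling parameters (empty list until scaled)
#' @export
setMethod("scalingParams", "CohortTable", function(x) x@scalingParams)

#' Subset a cohort by records (i) and/or features (j)
#'
#' @param x a [CohortTable-class].
#' @param i record indices.
#' @param j feature indices or names.
#' @param ... ignored.
#' @param drop ignored (always FALSE).
#' @export
setMethod("[", "CohortTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  if (is.character(j)) j <- match(j, colnames(x@values))
  if (anyNA(j)) stop("unknown feature name in subset")
  sp <- x@scalingParams
  if (length(sp)) sp <- sp[colnames(x@values)[j]]
  initialize(x, values = x@values[i, j, drop = FALSE],
             outcome = x@outcome[i], ids = x@ids[i],
             featureInfo = x@featureInfo[j, , drop = FALSE],
             scalingParams = sp)
})

setMethod("show", "CohortTable", function(object) {
  cat("CohortTable:", nrow(object@values), "records x",
      ncol(object@values), "features",
      if (object@scaled) "(scaled to [0,1])" else "(unscaled)", "\n")
  cat("  outcome: ", sum(object@outcome == 1), " high risk / ",
      sum(object@outcome == 0), " low risk\n", sep = "")
  cat("  features:", paste(utils::head(colnames(object@values), 8), collapse = ", "),
      if (ncol(object@values) > 8) "...", "\n")
})

setMethod("show", "ExclusionReport", function(object) {
  cat("ExclusionReport: ", object@nRaw, " raw - ", object@nExcludedMissing,
      " missing - ", object@nExcludedAge, " under-age = ", object@nFinal,
      " final\n", sep = "")
})
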