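#' Sensitivity-change matrix under single-feature amplification
#'
#' For every feature j, the whole dataset is amplified by adding a small
#' delta to column j; the sensitivity of every feature i is recomputed on the
#' amplified dataset and compared with its baseline value:
#' cell(i, j) = | Sen(X with x_j + delta, x_i) - Sen(X, x_i) |.
#' The same per-feature seeded deltas are used for the inner sensitivity
#' computations on both datasets, so the cell isolates the effect of the
#' amplification. Column means are taken over all rows, diagonal included.
#'
#' @param net a [TrainedNetwork-class] trained on the table's features.
#' @param table a scaled [CohortTable-class].
#' @param pert a [perturbationSpec()]; the amplification delta of feature j
#'   is the same seeded draw as its sensitivity delta.
#' @return a [SensitivityChangeMatrix-class].
#' @export
sensitivityChangeMatrix <- function(net, table, pert = perturbationSpec()) {
  fn <- colnames(table@values)
  f <- length(fn)
  deltas <- vapply(seq_len(f), function(k) .drawDelta(pert, k), 0)
  base <- vapply(seq_len(f), function(i)
    .sensitivityWithDelta(net, table, i, deltas[i]), 0)
  cells <- matrix(0, f, f, dimnames = list(fn, fn))
  for (j in seq_len(f)) {
    amp <- perturbFeature(table, fn[j], deltas[j])
    for (i in seq_len(f))
      cells[i, j] <- abs(.sensitivityWithDelta(net, amp, i, deltas[i]) - base[i])
  }
  new("SensitivityChangeMatrix", featureNames = fn, cells = cells,
      columnMeans = colMeans(cells))
}

#' Read a sensitivity-change matrix from CSV
#'
#' Layout: first column holds the measured-feature names, the header names
#' the amplified features. A row labelled "Average" is read as the stored
#' column means and kept as authoritative (published tables round to three
#' decimals, so stored means may differ slightly from recomputed ones);
#' without it the means are recomputed from the cells.
#'
#' @param path CSV path.
#' @return a [SensitivityChangeMatrix-class].
#' @export
readSensitivityChangeMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  avgRow <- match("Average", rn)
  if (!is.na(avgRow)) {
    columnMeans <- as.numeric(m[avgRow, ])
    m <- m[-avgRow, , drop = FALSE]
    rn <- rn[-avgRow]
  } else {
    columnMeans <- colMeans(m)
  }
  if (!identical(rn, colnames(m)))
    stop("row and column feature names must match")
  storage.mode(m) <- "numeric"
  rownames(m) <- rn
  new("SensitivityChangeMatrix", featureNames = rn, cells = m,
      columnMeans = columnMeans)
}

#' Write a sensitivity-change matrix as CSV (with an Average row)
#' @param matrix a [SensitivityChangeMatrix-class].
#' @param path output path.
#' @export
writeSensitivityChangeMatrix <- function(matrix, path) {
  df <- data.frame(feature = c(matrix@featureNames, "Average"),
                   rbind(matrix@cells, matrix@columnMeans),
                   check.names = FALSE)
  colnames(df) <- c("feature", matrix@featureNames)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Candidate correlates per amplified feature
#'
#' Feature i (i != j) is a candidate correlate of j when its sensitivity
#' change under amplification of j meets or exceeds the column-j average
#' (within an optional tolerance that absorbs the rounding of published
#' reference matrices). The amplified feature is never its own candidate.
#'
#' @param matrix a [SensitivityChangeMatrix-class].
#' @param tol threshold tolerance. The default 0 applies the rule exactly,
#'   which is right for full-precision computed matrices; use about 5e-4 when
#'   the matrix was read from a table printed at three decimals, so candidacy
#'   is not lost to rounding.
#' @return named list: for each feature, the character vector of candidates.
#' @export
columnCandidates <- function(matrix, tol = 0) {
  stopifnot(is(matrix, "SensitivityChangeMatrix"))
  fn <- matrix@featureNames
  out <- lapply(seq_along(fn), function(j) {
    hit <- matrix@cells[, j] >= matrix@columnMeans[j] - tol
    fn[hit & fn != fn[j]]
  })
  stats::setNames(out, fn)
}

#' Mutual correlated pairs and their groups
#'
#' Pair {i, j} is declared correlated iff i is a candidate under
#' amplification of j AND j is a candidate under amplification of i
#' (one-directional candidacy is insufficient). Groups are the connected
#' components of the pair graph; features in no pair are singleton groups.
#'
#' @param candidates the named list from [columnCandidates()].
#' @return a [CorrelationGraph-class]. Pair members and rows are ordered by
#'   feature position, so the result is invariant to feature ordering.
#' @export
mutualPairs <- function(candidates) {
  fn <- names(candidates)
  pairs <- matrix(character(0), 0, 2)
  for (a in seq_along(fn)) {
    for (b in seq_along(fn)) {
      if (b <= a) next
      if (fn[b] %in% candidates[[a]] && fn[a] %in% candidates[[b]])
        pairs <- rbind(pairs, c(fn[a], fn[b]))
    }
  }
  if (nrow(pairs) > 0) {
    g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
    comp <- igraph::components(g)
    grouped <- split(names(comp$membership), comp$membership)
    grouped <- lapply(grouped, function(gr) gr[order(match(gr, fn))])
  } else {
    grouped <- list()
  }
  singles <- setdiff(fn, unlist(grouped))
  groups <- c(grouped, as.list(singles))
  # canonical order: by first member's position in fn
  groups <- groups[order(vapply(groups, function(g) min(match(g, fn)), 0))]
  names(groups) <- NULL
  new("CorrelationGraph", featureNames = fn, pairs = pairs, groups = groups)
}

#' Build the coupled-connection network topology from correlation groups
#'
#' The hidden layer is partitioned into one block of `hiddenPerGroup` units
#' per correlation group; the mask connects a group's features only to its
#' own block (correlated features share hidden units — a coupled connection —
#' while uncorrelated features stay decoupled). All hidden units connect to
#' the single output. With no pairs and hiddenPerGroup = 1 the mask is
#' diagonal; with all features in one group it is dense.
#'
#' @param graph a [CorrelationGraph-class].
#' @param hiddenPerGroup hidden units allocated to each group (>= 1).
#' @return a [NetworkSpec-class].
#' @export
buildGroupMask <- function(graph, hiddenPerGroup = 1L) {
  stopifnot(is(graph, "CorrelationGraph"))
  if (hiddenPerGroup < 1) stop("hiddenPerGroup must be >= 1")
  fn <- graph@featureNames
  if (length(fn) == 0) stop("empty graph: no features")
  groups <- graph@groups
  nHidden <- length(groups) * hiddenPerGroup
  mask <- matrix(0, length(fn), nHidden, dimnames = list(fn, NULL))
  for (g in seq_along(groups)) {
    cols <- (g - 1L) * hiddenPerGroup + seq_len(hiddenPerGroup)
    mask[match(groups[[g]], fn), cols] <- 1
  }
  networkSpec(fn, nHidden = nHidden, mask = mask)
}

#' Serialize candidate sets and pairs to JSON
#' @param candidates list from [columnCandidates()].
#' @param graph a [CorrelationGraph-class].
#' @param path optional file path; when NULL the JSON string is returned.
#' @export
writeCorrelationJson <- function(candidates, graph, path = NULL) {
  x <- list(candidates = candidates,
            pairs = apply(graph@pairs, 1, function(p) list(p[1], p[2])),
            groups = graph@groups)
  if (is.null(path)) return(jsonlite::toJSON(x, auto_unbox = TRUE))
  jsonlite::write_json(x, path, auto_unbox = TRUE)
  invisible(path)
}

#' @describeIn SensitivityChangeMatrix the F x F cell matrix
#' @param x a SensitivityChangeMatrix
#' @export
setMethod("changeCells", "SensitivityChangeMatrix", function(x) x@cells)

#' @describeIn SensitivityChangeMatrix per-column average sensitivity change
#' @export
setMethod("columnAverages", "SensitivityChangeMatrix", function(x) {
  stats::setNames(x@columnMeans, x@featureNames)
})

#' @describeIn SensitivityChangeMatrix feature names
#' @export
setMethod("featureNames", "SensitivityChangeMatrix", function(x) x@featureNames)

#' @describeIn CorrelationGraph two-column matrix of correlated pairs
#' @param x a CorrelationGraph
#' @export
setMethod("correlatedPairs", "CorrelationGraph", function(x) x@pairs)

#' @describeIn CorrelationGraph list of feature groups (connected components
#'   plus singletons)
#' @export
setMethod("featureGroups", "CorrelationGraph", function(x) x@groups)

#' @describeIn CorrelationGraph feature names
#' @export
setMethod("featureNames", "CorrelationGraph", function(x) x@featureNames)

setMethod("show", "SensitivityChangeMatrix", function(object) {
  cat("SensitivityChangeMatrix:", length(object@featureNames), "x",
      length(object@featureNames), "(rows = measured, columns = amplified)\n")
})

setMethod("show", "CorrelationGraph", function(object) {
  cat("CorrelationGraph:", nrow(object@pairs), "pair(s),",
      length(object@groups), "group(s)\n")
  if (nrow(object@pairs))
    cat(paste0("  ", object@pairs[, 1], " -- ", object@pairs[, 2], "\n"), sep = "")
})
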