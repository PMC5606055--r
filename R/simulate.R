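#' Configuration for the synthetic cohort generator
#'
#' Gaussian-copula-style generation: all features start as correlated
#' standard-normal latents (pairwise correlations from `correlatedPairs`),
#' then receive their marginal form — continuous features as mean + sd * z
#' clamped to their bounds, binary features by thresholding the latent at the
#' configured prevalence, ordinal features by cutting the latent at the
#' cumulative level probabilities. The binary outcome is Bernoulli with
#' logit = intercept + sum(effect_f * scaled feature) + sum(interaction *
#' scaled_a * scaled_b), where "scaled" means min-max over the configured
#' bounds, so effects are log-odds per full feature range.
#'
#' @param nRecords number of records (>= 50).
#' @param features list of per-feature specs, each a list with `name`, `kind`
#'   and, per kind: continuous `mean`, `sd`, `lo`, `hi`; binary `prevalence`;
#'   ordinal `probs` (level probabilities summing to 1).
#' @param effects named numeric vector of log-odds coefficients on the
#'   (scaled) features; omitted features have effect 0.
#' @param correlatedPairs data.frame with columns `a`, `b`, `rho` and
#'   `interaction` (joint log-odds on the scaled product), or NULL.
#' @param intercept log-odds intercept.
#' @param seed integer seed.
#' @return a validated simulation-config list.
#' @export
simulationConfig <- function(nRecords, features, effects = numeric(0),
                             correlatedPairs = NULL, intercept = 0,
                             seed = 1L) {
  if (nRecords < 50) stop("nRecords must be >= 50")
  fn <- vapply(features, `[[`, "", "name")
  if (anyDuplicated(fn)) stop("duplicate feature names")
  for (f in features) {
    if (!f$kind %in% c("continuous", "binary", "ordinal"))
      stop("unknown feature kind: ", f$kind)
    if (f$kind == "binary" && (f$prevalence <= 0 || f$prevalence >= 1))
      stop("prevalence must be in (0, 1)")
    if (f$kind == "ordinal" && abs(sum(f$probs) - 1) > 1e-8)
      stop("ordinal level probabilities must sum to 1")
    if (f$kind == "continuous" && f$lo >= f$hi)
      stop("continuous bounds need lo < hi")
  }
  if (!is.null(correlatedPairs)) {
    if (!all(c("a", "b", "rho", "interaction") %in% colnames(correlatedPairs)))
      stop("correlatedPairs needs columns a, b, rho, interaction")
    if (any(abs(correlatedPairs$rho) >= 1)) stop("|rho| must be < 1")
    if (!all(c(correlatedPairs$a, correlatedPairs$b) %in% fn))
      stop("correlated pair members must be features")
  }
  if (length(effects) && !all(names(effects) %in% fn))
    stop("effects must be named after features")
  structure(list(nRecords = as.integer(nRecords), features = features,
                 effects = effects, correlatedPairs = correlatedPairs,
                 intercept = intercept, seed = as.integer(seed)),
            class = "nnfca_simulationConfig")
}

.latentCorrelation <- function(config) {
  fn <- vapply(config$features, `[[`, "", "name")
  R <- diag(length(fn))
  dimnames(R) <- list(fn, fn)
  cp <- config$correlatedPairs
  if (!is.null(cp)) {
    for (k in seq_len(nrow(cp))) {
      R[cp$a[k], cp$b[k]] <- cp$rho[k]
      R[cp$b[k], cp$a[k]] <- cp$rho[k]
    }
  }
  R
}

# latents -> feature values and unit-scaled values, given the config
.materialize <- function(config, Z) {
  n <- nrow(Z)
  fn <- vapply(config$features, `[[`, "", "name")
  values <- matrix(0, n, length(fn), dimnames = list(NULL, fn))
  scaled <- values
  for (k in seq_along(config$features)) {
    f <- config$features[[k]]
    z <- Z[, k]
    if (f$kind == "continuous") {
      x <- pmin(pmax(f$mean + f$sd * z, f$lo), f$hi)
      values[, k] <- x
      scaled[, k] <- (x - f$lo) / (f$hi - f$lo)
    } else if (f$kind == "binary") {
      x <- as.numeric(z > stats::qnorm(1 - f$prevalence))
      values[, k] <- x
      scaled[, k] <- x
    } else {
      cuts <- c(0, cumsum(f$probs))
      cuts[length(cuts)] <- 1
      x <- as.numeric(cut(stats::pnorm(z), cuts, labels = FALSE,
                          include.lowest = TRUE)) - 1
      values[, k] <- x
      scaled[, k] <- x / (length(f$probs) - 1)
    }
  }
  list(values = values, scaled = scaled)
}

.linearPredictor <- function(config, scaled) {
  lp <- rep(config$intercept, nrow(scaled))
  for (nm in names(config$effects))
    lp <- lp + config$effects[[nm]] * scaled[, nm]
  cp <- config$correlatedPairs
  if (!is.null(cp)) {
    for (k in seq_len(nrow(cp)))
      if (cp$interaction[k] != 0)
        lp <- lp + cp$interaction[k] * scaled[, cp$a[k]] * scaled[, cp$b[k]]
  }
  lp
}

#' Simulate a cohort with planted ground truth
#'
#' @param config a [simulationConfig()].
#' @return list with `table` (an unscaled [CohortTable-class]) and `truth`
#'   (planted informative features, correlated pairs, intercept and the
#'   realized outcome prevalence).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "nnfca_simulationConfig"))
  R <- .latentCorrelation(config)
  U <- tryCatch(chol(R), error = function(e)
    stop("configuration error: correlation structure is not positive definite"))
  n <- config$nRecords
  fn <- vapply(config$features, `[[`, "", "name")
  sim <- withr::with_seed(config$seed, {
    Z <- matrix(stats::rnorm(n * length(fn)), n) %*% U
    m <- .materialize(config, Z)
    y <- stats::rbinom(n, 1, stats::plogis(.linearPredictor(config, m$scaled)))
    list(values = m$values, y = y)
  })
  specs <- lapply(config$features, function(f) {
    switch(f$kind,
      continuous = featureSpec(f$name, "continuous", validRange = c(f$lo, f$hi)),
      binary = featureSpec(f$name, "binary", levels = c("no", "yes")),
      ordinal = featureSpec(f$name, "ordinal",
                            levels = paste0("level", seq_along(f$probs) - 1)))
  })
  informative <- names(config$effects)[unlist(config$effects) != 0]
  cp <- config$correlatedPairs
  truth <- list(
    informative = informative,
    correlatedPairs = if (is.null(cp)) NULL else cp[, c("a", "b", "rho", "interaction")],
    intercept = config$intercept,
    prevalence = mean(sim$y)
  )
  list(table = cohortTable(sim$values, sim$y, specs), truth = truth)
}

#' Calibrate the outcome intercept to a target prevalence
#'
#' Bisection on the intercept so the mean outcome probability over a large
#' seeded probe draw of the features hits the target within `tol`.
#'
#' @param config a [simulationConfig()] (its intercept is ignored).
#' @param target target outcome prevalence.
#' @param tol acceptable absolute deviation.
#' @param nProbe probe-draw size.
#' @return the calibrated intercept (numeric).
#' @export
calibrateIntercept <- function(config, target, tol = 0.01, nProbe = 20000L) {
  R <- .latentCorrelation(config)
  U <- chol(R)
  fn <- vapply(config$features, `[[`, "", "name")
  scaled <- withr::with_seed(config$seed, {
    Z <- matrix(stats::rnorm(nProbe * length(fn)), nProbe) %*% U
    .materialize(config, Z)$scaled
  })
  probe <- config
  prevAt <- function(b0) {
    probe$intercept <- b0
    mean(stats::plogis(.linearPredictor(probe, scaled)))
  }
  lo <- -20; hi <- 20
  for (it in 1:100) {
    mid <- (lo + hi) / 2
    p <- prevAt(mid)
    if (abs(p - target) <= tol / 2) return(mid)
    if (p < target) lo <- mid else hi <- mid
  }
  mid
}

#' Default synthetic cohort emulating a national health-survey CHD table
#'
#' Nine features at the marginal scales of the selected CHD feature set (age,
#' BMI, total cholesterol, HDL, SBP, DBP, triglyceride, smoking, diabetes),
#' with planted log-odds effects on age, SBP and diabetes, a planted
#' SBP-DBP correlation of rho = 0.7 carrying a joint log-odds interaction
#' sized at the scale of the largest main effect (so the pair genuinely
#' drives the outcome jointly), and the intercept calibrated so the
#' high-risk fraction is about 0.269.
#'
#' @param nRecords cohort size (default 4146).
#' @param seed integer seed.
#' @return a [simulationConfig()].
#' @export
defaultCohortConfig <- function(nRecords = 4146L, seed = 20170906L) {
  cont <- function(name, mean, sd, lo, hi)
    list(name = name, kind = "continuous", mean = mean, sd = sd, lo = lo, hi = hi)
  features <- list(
    cont("age", 52.5, 12, 30, 92),
    cont("BMI", 23.97, 3.2, 15, 42),
    cont("To_chole", 191, 36, 79, 525),
    cont("HDL", 51.8, 12, 22, 118),
    cont("SBP", 119, 16, 75, 219),
    cont("DBP", 75.8, 10, 40, 137),
    cont("triglyceride", 139, 70, 20, 1868),
    list(name = "smoking", kind = "binary", prevalence = 824 / 4146),
    list(name = "diabetes", kind = "ordinal",
         probs = c(2625, 994, 527) / 4146)
  )
  config <- simulationConfig(
    nRecords = nRecords,
    features = features,
    effects = c(age = 2.5, SBP = 2.0, diabetes = 1.5),
    correlatedPairs = data.frame(a = "SBP", b = "DBP", rho = 0.7,
                                 interaction = 2.5, stringsAsFactors = FALSE),
    intercept = 0,
    seed = seed
  )
  config$intercept <- calibrateIntercept(config, target = 1115 / 4146)
  config
}

#' Serialize a simulation config to JSON
#' @param config a [simulationConfig()].
#' @param path optional file path; when NULL the JSON string is returned.
#' @export
configToJson <- function(config, path = NULL) {
  x <- unclass(config)
  x$effects <- as.list(x$effects)
  if (is.null(path)) return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Restore a simulation config from JSON
#' @param path file path or JSON string produced by [configToJson()].
#' @export
configFromJson <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  features <- lapply(x$features, function(f) lapply(f, function(v)
    if (is.list(v)) unlist(v) else v))
  cp <- NULL
  if (!is.null(x$correlatedPairs) && length(x$correlatedPairs)) {
    cp <- do.call(rbind, lapply(x$correlatedPairs, function(row)
      data.frame(a = row$a, b = row$b, rho = row$rho,
                 interaction = row$interaction, stringsAsFactors = FALSE)))
  }
  simulationConfig(
    nRecords = x$nRecords,
    features = features,
    effects = unlist(x$effects),
    correlatedPairs = cp,
    intercept = x$intercept,
    seed = x$seed
  )
}
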