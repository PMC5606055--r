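#' Training configuration for backpropagation
#'
#' Full-batch gradient descent on the mean cross-entropy loss, logistic
#' activations throughout. The defaults were sized so that a network on a
#' unit-scaled cohort of a few thousand records converges (monotone loss) in
#' well under a second.
#'
#' @param learningRate positive step size.
#' @param epochs number of full-batch gradient steps (>= 0; 0 leaves the
#'   network untouched).
#' @param seed integer seed for weight initialization.
#' @param initScale weights drawn uniformly in +/- initScale.
#' @return a validated config list.
#' @export
trainingConfig <- function(learningRate = 2, epochs = 600L, seed = 1L,
                           initScale = 0.5) {
  if (learningRate <= 0) stop("learningRate must be positive")
  if (epochs < 0) stop("epochs must be >= 0")
  if (initScale <= 0) stop("initScale must be positive")
  structure(list(learningRate = learningRate, epochs = as.integer(epochs),
                 seed = as.integer(seed), initScale = initScale),
            class = "nnfca_trainingConfig")
}

#' Build a network topology
#'
#' @param featureNames input feature names (determines nInput).
#' @param nHidden hidden-unit count.
#' @param mask binary nInput x nHidden connectivity matrix; default all ones
#'   (a standard dense multilayer perceptron).
#' @return a [NetworkSpec-class].
#' @export
networkSpec <- function(featureNames, nHidden = 4L, mask = NULL) {
  nInput <- length(featureNames)
  if (is.null(mask)) mask <- matrix(1, nInput, nHidden)
  new("NetworkSpec", nInput = as.integer(nInput), nHidden = as.integer(nHidden),
      mask = mask, activation = "logistic", featureNames = featureNames)
}

#' Initialize network weights
#'
#' Unmasked weights and all biases are drawn uniformly in +/- initScale from
#' the seeded generator; masked weights are exactly zero.
#'
#' @param spec a [NetworkSpec-class].
#' @param config a [trainingConfig()].
#' @return a [TrainedNetwork-class] (untrained).
#' @export
initNetwork <- function(spec, config = trainingConfig()) {
  stopifnot(is(spec, "NetworkSpec"))
  s <- config$initScale
  draws <- withr::with_seed(config$seed, {
    list(W = matrix(stats::runif(spec@nInput * spec@nHidden, -s, s),
                    spec@nInput, spec@nHidden),
         bHidden = stats::runif(spec@nHidden, -s, s),
         wOut = stats::runif(spec@nHidden, -s, s),
         bOut = stats::runif(1, -s, s))
  })
  draws$W[spec@mask == 0] <- 0
  new("TrainedNetwork", spec = spec, W = draws$W, bHidden = draws$bHidden,
      wOut = draws$wOut, bOut = draws$bOut,
      config = unclass(config), lossHistory = numeric(0))
}

.forwardMatrix <- function(net, X) {
  n <- nrow(X)
  H <- stats::plogis(X %*% net@W +
                     matrix(net@bHidden, n, length(net@bHidden), byrow = TRUE))
  list(H = H, p = stats::plogis(drop(H %*% net@wOut) + net@bOut))
}

#' Forward pass: predicted risk probability
#'
#' output = sigma(wOut . sigma(W' x + bHidden) + bOut), deterministic, always
#' in (0, 1) for finite inputs.
#'
#' @param net a [TrainedNetwork-class].
#' @param x a feature vector of length nInput, a records x features matrix,
#'   or a [CohortTable-class].
#' @return numeric vector of probabilities.
#' @export
forward <- function(net, x) {
  stopifnot(is(net, "TrainedNetwork"))
  if (is(x, "CohortTable")) x <- x@values
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != net@spec@nInput)
    stop("input has ", ncol(x), " features; network expects ", net@spec@nInput)
  .forwardMatrix(net, x)$p
}

.crossEntropy <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train a (masked) network by backpropagation
#'
#' Full-batch gradient descent on the mean cross-entropy loss. Gradients at
#' masked input-to-hidden positions are forced to zero every step, so masked
#' weights stay exactly zero throughout. The table should be scaled to the
#' unit interval and must contain both outcome classes.
#'
#' @param net an initialized [TrainedNetwork-class].
#' @param table a scaled [CohortTable-class].
#' @param config a [trainingConfig()]; defaults to the config stored at
#'   initialization.
#' @return the trained [TrainedNetwork-class], with per-epoch losses in
#'   its loss history.
#' @export
trainNetwork <- function(net, table, config = NULL) {
  stopifnot(is(net, "TrainedNetwork"), is(table, "CohortTable"))
  if (is.null(config)) config <- net@config
  config <- unclass(config)
  if (length(unique(table@outcome)) < 2)
    stop("training requires both outcome classes")
  X <- table@values
  if (ncol(X) != net@spec@nInput)
    stop("table has ", ncol(X), " features; network expects ", net@spec@nInput)
  y <- table@outcome
  n <- nrow(X)
  maskZero <- net@spec@mask == 0
  W <- net@W; b1 <- net@bHidden; w2 <- net@wOut; b2 <- net@bOut
  lr <- config$learningRate
  epochs <- config$epochs
  losses <- numeric(epochs)
  if (epochs > 0) {
    for (e in seq_len(epochs)) {
      H <- stats::plogis(X %*% W + matrix(b1, n, length(b1), byrow = TRUE))
      p <- stats::plogis(drop(H %*% w2) + b2)
      losses[e] <- .crossEntropy(p, y)
      if (!is.finite(losses[e]))
        stop("training diverged (non-finite loss) at epoch ", e)
      d2 <- (p - y) / n
      gw2 <- drop(crossprod(H, d2))
      gb2 <- sum(d2)
      dH <- (d2 %o% w2) * H * (1 - H)
      gW <- crossprod(X, dH)
      gW[maskZero] <- 0
      W <- W - lr * gW
      b1 <- b1 - lr * colSums(dH)
      w2 <- w2 - lr * gw2
      b2 <- b2 - lr * gb2
    }
  }
  initialize(net, W = W, bHidden = b1, wOut = w2, bOut = b2,
             config = config, lossHistory = c(net@lossHistory, losses))
}

#' Classification accuracy of a network on a cohort (percent)
#'
#' @param net a [TrainedNetwork-class].
#' @param table a [CohortTable-class].
#' @param threshold classification cutoff on the predicted probability.
#' @export
networkAccuracy <- function(net, table, threshold = 0.5) {
  p <- forward(net, table)
  100 * mean((p >= threshold) == (table@outcome == 1))
}

#' Serialize a network to JSON
#' @param net a [TrainedNetwork-class].
#' @param path optional file path; when NULL the JSON string is returned.
#' @export
networkToJson <- function(net, path = NULL) {
  x <- list(
    spec = list(n_input = net@spec@nInput, n_hidden = net@spec@nHidden,
                mask = net@spec@mask, activation = net@spec@activation,
                feature_names = net@spec@featureNames),
    W = net@W, b_hidden = net@bHidden, w_out = net@wOut, b_out = net@bOut,
    config = net@config
  )
  if (is.null(path)) return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a network from JSON
#' @param path file path or JSON string produced by [networkToJson()].
#' @return a [TrainedNetwork-class].
#' @export
networkFromJson <- function(path) {
  x <- jsonlite::fromJSON(path)
  spec <- new("NetworkSpec", nInput = as.integer(x$spec$n_input),
              nHidden = as.integer(x$spec$n_hidden),
              mask = matrix(as.numeric(x$spec$mask), x$spec$n_input, x$spec$n_hidden),
              activation = x$spec$activation,
              featureNames = as.character(x$spec$feature_names))
  new("TrainedNetwork", spec = spec,
      W = matrix(as.numeric(x$W), x$spec$n_input, x$spec$n_hidden),
      bHidden = as.numeric(x$b_hidden), wOut = as.numeric(x$w_out),
      bOut = as.numeric(x$b_out), config = as.list(x$config),
      lossHistory = numeric(0))
}

# ---- accessors & show --------------------------------------------------------

#' @describeIn NetworkSpec the binary connectivity mask
#' @param x a NetworkSpec or TrainedNetwork
#' @export
setMethod("connectionMask", "NetworkSpec", function(x) x@mask)

#' @describeIn TrainedNetwork the spec's connectivity mask
#' @param x a TrainedNetwork
#' @export
setMethod("connectionMask", "TrainedNetwork", function(x) x@spec@mask)

#' @describeIn TrainedNetwork input-to-hidden weight matrix
#' @export
setMethod("inputWeights", "TrainedNetwork", function(x) x@W)

#' @describeIn TrainedNetwork hidden-to-output weights
#' @export
setMethod("outputWeights", "TrainedNetwork", function(x) x@wOut)

#' @describeIn NetworkSpec input feature names
#' @export
setMethod("featureNames", "NetworkSpec", function(x) x@featureNames)

#' @describeIn TrainedNetwork input feature names
#' @export
setMethod("featureNames", "TrainedNetwork", function(x) x@spec@featureNames)

setMethod("show", "NetworkSpec", function(object) {
  cat("NetworkSpec: ", object@nInput, "-", object@nHidden, "-1 (",
      sum(object@mask), "/", length(object@mask),
      " input connections active)\n", sep = "")
})

setMethod("show", "TrainedNetwork", function(object) {
  show(object@spec)
  cat("  trained epochs:", length(object@lossHistory))
  if (length(object@lossHistory))
    cat(", final loss:", signif(utils::tail(object@lossHistory, 1), 4))
  cat("\n")
})
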