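# Independent oracles: explicit loops, no shared code with the package.

denseForwardOracle <- function(W, bHidden, wOut, bOut, x) {
  h <- numeric(length(bHidden))
  for (j in seq_along(h)) h[j] <- 1 / (1 + exp(-(sum(W[, j] * x) + bHidden[j])))
  1 / (1 + exp(-(sum(wOut * h) + bOut)))
}

bruteCounts <- function(labels, scores, threshold) {
  tp <- fp <- fn <- tn <- 0
  for (k in seq_along(labels)) {
    predPos <- scores[k] >= threshold
    if (predPos && labels[k] == 1) tp <- tp + 1
    if (predPos && labels[k] == 0) fp <- fp + 1
    if (!predPos && labels[k] == 1) fn <- fn + 1
    if (!predPos && labels[k] == 0) tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

bruteAuc <- function(labels, scores) {
  posScores <- scores[labels == 1]
  negScores <- scores[labels == 0]
  total <- 0
  for (p in posScores) for (n in negScores)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(posScores) * length(negScores))
}

# One gradient-descent step at learning rate 1 recovers the analytic
# gradients; compare them with central finite differences of the
# cross-entropy loss evaluated through the independent forward oracle.
# Returns the maximum relative error over all parameters.
maxGradientRelError <- function(net, tab, h = 1e-6) {
  cfg <- trainingConfig(learningRate = 1, epochs = 1,
                        seed = net@config$seed %||% 1L)
  stepped <- trainNetwork(net, tab, cfg)
  gradW <- net@W - stepped@W
  gradB1 <- net@bHidden - stepped@bHidden
  gradW2 <- net@wOut - stepped@wOut
  gradB2 <- net@bOut - stepped@bOut

  X <- featureMatrix(tab); y <- outcome(tab)
  loss <- function(W, b1, w2, b2) {
    p <- vapply(seq_len(nrow(X)), function(k)
      denseForwardOracle(W, b1, w2, b2, X[k, ]), 0)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  relErr <- function(a, b) abs(a - b) / max(abs(a), 1e-8)
  worst <- 0
  maskOne <- net@spec@mask == 1
  for (i in seq_len(nrow(net@W))) for (j in seq_len(ncol(net@W))) {
    if (!maskOne[i, j]) next  # masked gradients are defined to be zero
    Wp <- net@W; Wm <- net@W
    Wp[i, j] <- Wp[i, j] + h; Wm[i, j] <- Wm[i, j] - h
    fd <- (loss(Wp, net@bHidden, net@wOut, net@bOut) -
           loss(Wm, net@bHidden, net@wOut, net@bOut)) / (2 * h)
    worst <- max(worst, relErr(gradW[i, j], fd))
  }
  for (j in seq_along(net@bHidden)) {
    bp <- net@bHidden; bm <- net@bHidden
    bp[j] <- bp[j] + h; bm[j] <- bm[j] - h
    fd <- (loss(net@W, bp, net@wOut, net@bOut) -
           loss(net@W, bm, net@wOut, net@bOut)) / (2 * h)
    worst <- max(worst, relErr(gradB1[j], fd))
    wp <- net@wOut; wm <- net@wOut
    wp[j] <- wp[j] + h; wm[j] <- wm[j] - h
    fd <- (loss(net@W, net@bHidden, wp, net@bOut) -
           loss(net@W, net@bHidden, wm, net@bOut)) / (2 * h)
    worst <- max(worst, relErr(gradW2[j], fd))
  }
  fd <- (loss(net@W, net@bHidden, net@wOut, net@bOut + h) -
         loss(net@W, net@bHidden, net@wOut, net@bOut - h)) / (2 * h)
  max(worst, relErr(gradB2, fd))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
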