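#' Generate Memory Capacity task data
#'
#' A single input channel `x(t) ~ Uniform(-0.5, 0.5)` with one target per
#' lag: `y[t, k] = x[t - lags[k]]`. Entries with `t <= lag` are undefined
#' and set to NA; they are excluded from fitting and scoring (the 100-step
#' transient removes them in practice). Train/test splits are contiguous:
#' the first `tTrain` steps train, the next `tTest` test.
#'
#' @param T total series length (train + test)
#' @param lags strictly increasing positive integer lags (default 1:40)
#' @param seed integer seed (NULL = current RNG stream)
#' @return a [MemoryCapacityData-class]
#' @export
makeMemoryCapacityData <- function(T, lags = 1:40, seed = NULL) {
  checkScalar(T, "T", lower = 2, integer = TRUE)
  if (!length(lags) || any(lags < 1) || any(lags != round(lags)) ||
      is.unsorted(lags, strictly = TRUE))
    validationError("`lags` must be strictly increasing positive integers")
  if (T <= max(lags))
    degenerateError(sprintf("T = %d must exceed max(lags) = %d",
                            as.integer(T), max(lags)))
  lags <- as.integer(lags)
  x <- withSeed(seed, matrix(runif(T, -0.5, 0.5), ncol = 1))
  y <- matrix(NA_real_, T, length(lags))
  for (k in seq_along(lags)) {
    tau <- lags[k]
    y[(tau + 1):T, k] <- x[1:(T - tau), 1]
  }
  new("MemoryCapacityData", x = x, y = y, lags = lags)
}

# squared Pearson correlation; a constant series carries no memory content,
# so its score is defined as 0
rho2 <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)^2
}

#' Score Memory Capacity
#'
#' Per-lag score is the squared Pearson correlation between target and
#' prediction; the Memory Capacity is their sum over lags (the forgetting
#' curve integrated over the lag set). Rows are expected to be already
#' restricted to scored steps (transient and undefined entries removed).
#'
#' @param y T x n_lags target matrix
#' @param yHat T x n_lags prediction matrix
#' @param lags the lag labels (length must match the columns)
#' @return an [EvalResult-class] with `perOutput` the per-lag forgetting
#'   curve and `aggregate` the MC
#' @export
scoreMemoryCapacity <- function(y, yHat, lags = seq_len(ncol(y))) {
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  if (is.null(dim(yHat))) yHat <- matrix(yHat, ncol = 1)
  if (!all(dim(y) == dim(yHat)))
    validationError("y and yHat must have identical dimensions")
  if (ncol(y) != length(lags))
    validationError("length(lags) must equal the number of target columns")
  scores <- vapply(seq_len(ncol(y)), function(k) {
    ok <- !is.na(y[, k])
    if (sum(ok) < 3) return(0)
    rho2(y[ok, k], yHat[ok, k])
  }, numeric(1))
  names(scores) <- paste0("lag_", lags)
  new("EvalResult", perOutput = scores, aggregate = sum(scores),
      nScored = as.integer(nrow(y)), task = "memory-capacity", info = list())
}

#' Generate Sequence Recall task data
#'
#' Each trial is `fixationLen` fixation steps (cue `x2 = 0`, sequence
#' input `x1 ~ Uniform(0, 1)`, target 0) followed by `patternLength`
#' recall steps (cue `x2 = 1`, `x1 = 0`, target = the last `patternLength`
#' fixation inputs in their original order). Trials are concatenated into
#' one continuous series per split.
#'
#' @param nTrials number of trials (>= 1)
#' @param patternLength pattern length L (task difficulty, >= 1)
#' @param fixationLen fixation steps per trial (>= L; default L, giving
#'   trials of length 2L)
#' @param seed integer seed (NULL = current RNG stream)
#' @return a [SequenceRecallData-class]
#' @export
makeSequenceRecallData <- function(nTrials, patternLength,
                                   fixationLen = patternLength,
                                   seed = NULL) {
  checkScalar(nTrials, "nTrials", lower = 1, integer = TRUE)
  checkScalar(patternLength, "patternLength", lower = 1, integer = TRUE)
  checkScalar(fixationLen, "fixationLen", lower = 1, integer = TRUE)
  L <- as.integer(patternLength); fl <- as.integer(fixationLen)
  if (fl < L)
    degenerateError(sprintf(
      "fixationLen = %d is shorter than patternLength = %d (pattern would be truncated)",
      fl, L))
  nTrials <- as.integer(nTrials)
  steps <- fl + L
  withSeed(seed, {
    x1fix <- matrix(runif(nTrials * fl), nrow = nTrials) # one row per trial
    x1 <- x2 <- y <- numeric(nTrials * steps)
    for (tr in seq_len(nTrials)) {
      o <- (tr - 1L) * steps
      x1[o + seq_len(fl)] <- x1fix[tr, ]
      x2[o + fl + seq_len(L)] <- 1
      y[o + fl + seq_len(L)] <- x1fix[tr, (fl - L + 1):fl]
    }
    trials <- data.frame(
      fixationStart = (seq_len(nTrials) - 1L) * steps + 1L,
      recallStart = (seq_len(nTrials) - 1L) * steps + fl + 1L,
      trialEnd = seq_len(nTrials) * steps)
    new("SequenceRecallData",
        x = cbind(x1 = x1, x2 = x2), y = matrix(y, ncol = 1),
        patternLength = L, fixationLen = fl, trials = trials)
  })
}

#' Recall-step indicator of a Sequence Recall dataset
#'
#' @param d a [SequenceRecallData-class]
#' @return logical vector, TRUE on recall steps (where the cue is 1)
#' @export
recallSteps <- function(d) d@x[, "x2"] == 1

#' Score Sequence Recall
#'
#' Pooled coefficient of determination over recall steps only:
#' `R^2 = 1 - SS_res / SS_tot`, with `SS_tot` about the mean of the true
#' recall targets. Fixation steps are excluded because they are trivially
#' easy and would inflate the score. The caller restricts `recall` to
#' post-transient steps.
#'
#' @param y target series (vector or 1-column matrix)
#' @param yHat prediction series
#' @param recall logical (or integer index) vector of the steps to score
#' @return an [EvalResult-class]; `aggregate` is the recall R^2 (<= 1)
#' @export
scoreSequenceRecall <- function(y, yHat, recall) {
  y <- as.numeric(y); yHat <- as.numeric(yHat)
  if (length(y) != length(yHat))
    validationError("y and yHat must have the same length")
  yt <- y[recall]; yp <- yHat[recall]
  if (!length(yt)) degenerateError("no recall steps to score")
  ssTot <- sum((yt - mean(yt))^2)
  if (ssTot == 0) degenerateError("recall targets are constant")
  r2 <- 1 - sum((yt - yp)^2) / ssTot
  new("EvalResult", perOutput = r2, aggregate = r2,
      nScored = length(yt), task = "sequence-recall", info = list())
}

setMethod("show", "EvalResult", function(object) {
  lab <- if (object@task == "memory-capacity") "MC" else "recall R^2"
  cat(sprintf("EvalResult (%s): %s = %.4f over %d scored steps\n",
              object@task, lab, object@aggregate, object@nScored))
  if (length(object@perOutput) > 1)
    cat(sprintf("  per-output scores: %s ...\n",
                paste(sprintf("%.3f", head(object@perOutput, 6)),
                      collapse = " ")))
})

#' Aggregate score of an evaluation
#' @param x an [EvalResult-class]
#' @return the aggregate score (MC or recall R^2)
#' @export
aggregateScore <- function(x) x@aggregate

#' Per-output scores of an evaluation (e.g. the forgetting curve)
#' @param x an [EvalResult-class]
#' @return named numeric vector
#' @export
perOutputScores <- function(x) x@perOutput

#' Train and evaluate a reservoir on the Memory Capacity task
#'
#' Generates the input series, runs the reservoir over the contiguous
#' training split, fits the pseudoinverse readout (transient discarded),
#' then re-initializes the state to zero for the test split and scores the
#' post-transient test steps per lag.
#'
#' @param W a [ReservoirMatrix-class] (after [scaleSpectralRadius()]) or
#'   plain square matrix
#' @param config an [ESNConfig-class]; the identity output activation is
#'   the appropriate choice for this task
#' @param lags lag set (default 1:40)
#' @param tTrain,tTest training and test lengths in steps (defaults 4000
#'   and 1000)
#' @param seed integer seed for the input series and input weights
#' @return an [EvalResult-class] (aggregate = MC, perOutput = forgetting
#'   curve)
#' @export
runMemoryCapacity <- function(W, config = esnConfig(), lags = 1:40,
                              tTrain = 4000, tTest = 1000, seed = NULL) {
  nr <- reservoirSize(if (is(W, "ReservoirMatrix")) weightMatrix(W) else W)
  withSeed(seed, {
    d <- makeMemoryCapacityData(tTrain + tTest, lags)
    Win <- initInputWeights(nr, 1)
    trainIdx <- seq_len(tTrain)
    testIdx <- tTrain + seq_len(tTest)
    xtr <- d@x[trainIdx, , drop = FALSE]
    xte <- d@x[testIdx, , drop = FALSE]
    str <- runReservoir(xtr, W, Win, config)
    ro <- fitReadout(xtr, str@states, d@y[trainIdx, , drop = FALSE], config)
    ste <- runReservoir(xte, W, Win, config) # state re-initialized to zero
    yhat <- predictOutput(xte, ste@states, ro)
    keep <- seq_len(tTest) > config@transient
    scoreMemoryCapacity(d@y[testIdx, , drop = FALSE][keep, , drop = FALSE],
                        yhat[keep, , drop = FALSE], d@lags)
  })
}

#' Train and evaluate a reservoir on the Sequence Recall task
#'
#' Generates `nTrainTrials + nTestTrials` trials, trains on the first
#' split (trials concatenated into one continuous series, transient
#' discarded), re-initializes the state to zero for the test split, and
#' scores the pooled R^2 over post-transient recall steps.
#'
#' @param W a [ReservoirMatrix-class] or plain square matrix
#' @param patternLength pattern length L (task difficulty)
#' @param config an [ESNConfig-class]; ReLU output is the appropriate
#'   choice since targets are non-negative
#' @param nTrainTrials,nTestTrials split sizes in trials (defaults 800 and
#'   200)
#' @param fixationLen fixation steps per trial (default `patternLength`)
#' @param seed integer seed for the trials and input weights
#' @return an [EvalResult-class] (aggregate = recall R^2)
#' @export
runSequenceRecall <- function(W, patternLength,
                              config = esnConfig(outputActivation = "relu"),
                              nTrainTrials = 800, nTestTrials = 200,
                              fixationLen = patternLength, seed = NULL) {
  nr <- reservoirSize(if (is(W, "ReservoirMatrix")) weightMatrix(W) else W)
  withSeed(seed, {
    d <- makeSequenceRecallData(nTrainTrials + nTestTrials, patternLength,
                                fixationLen)
    Win <- initInputWeights(nr, 2)
    steps <- d@fixationLen + d@patternLength
    trainIdx <- seq_len(nTrainTrials * steps)
    testIdx <- nTrainTrials * steps + seq_len(nTestTrials * steps)
    xtr <- d@x[trainIdx, , drop = FALSE]
    xte <- d@x[testIdx, , drop = FALSE]
    str <- runReservoir(xtr, W, Win, config)
    ro <- fitReadout(xtr, str@states, d@y[trainIdx, , drop = FALSE], config)
    ste <- runReservoir(xte, W, Win, config)
    yhat <- predictOutput(xte, ste@states, ro)
    recall <- recallSteps(d)[testIdx] & seq_along(testIdx) > config@transient
    scoreSequenceRecall(d@y[testIdx, 1], yhat[, 1], recall)
  })
}
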