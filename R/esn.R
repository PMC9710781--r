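#' Create an ESN hyperparameter configuration
#'
#' Defaults are the fixed post-tuning constellation used for all main
#' experiments: spectral radius 0.99, input scaling 1e-5, leakage 1
#' (no leakage), bias 1, tanh reservoir, 100-step transient discarded from
#' both training and testing.
#'
#' @param spectralRadius target spectral radius rho (> 0)
#' @param inputScaling input scaling factor epsilon; the input is scaled
#'   as `epsilon * x(t)` before the input weights
#' @param leakage leakage rate alpha in (0, 1]
#' @param bias scalar bias b (broadcast to all reservoir neurons)
#' @param reservoirActivation `"tanh"` (default) or `"identity"` (a
#'   diagnostic mode for linear-reservoir oracles)
#' @param outputActivation `"identity"` (Memory Capacity) or `"relu"`
#'   (Sequence Recall, whose targets are non-negative)
#' @param transient initial time steps discarded from fitting and scoring
#' @param seed provenance seed (optional)
#' @param leakIntegration `"standard"` (default) or `"printed"`; see
#'   [ESNConfig-class]. The two are identical at `leakage = 1`.
#' @return an [ESNConfig-class]
#' @export
esnConfig <- function(spectralRadius = 0.99, inputScaling = 1e-5,
                      leakage = 1, bias = 1,
                      reservoirActivation = c("tanh", "identity"),
                      outputActivation = c("identity", "relu"),
                      transient = 100, seed = NA,
                      leakIntegration = c("standard", "printed")) {
  checkScalar(spectralRadius, "spectralRadius", lower = .Machine$double.xmin)
  checkScalar(inputScaling, "inputScaling")
  checkScalar(leakage, "leakage", lower = .Machine$double.xmin, upper = 1)
  checkScalar(bias, "bias")
  checkScalar(transient, "transient", lower = 0, integer = TRUE)
  new("ESNConfig",
      spectralRadius = spectralRadius, inputScaling = inputScaling,
      leakage = leakage, bias = bias,
      reservoirActivation = match.arg(reservoirActivation),
      outputActivation = match.arg(outputActivation),
      transient = as.integer(transient),
      seed = if (is.na(seed)) NA_integer_ else as.integer(seed),
      leakIntegration = match.arg(leakIntegration))
}

setMethod("show", "ESNConfig", function(object) {
  cat(sprintf(
    paste0("ESNConfig: rho = %.3g, epsilon = %.3g, alpha = %.3g, ",
           "b = %.3g\n  f = %s, g = %s, transient = %d (%s leak form)\n"),
    object@spectralRadius, object@inputScaling, object@leakage, object@bias,
    object@reservoirActivation, object@outputActivation, object@transient,
    object@leakIntegration))
})

asInputMatrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (!is.numeric(x)) validationError("inputs must be numeric")
  if (any(!is.finite(x))) validationError("inputs contain non-finite values")
  x
}

#' Initialize dense input weights
#'
#' All reservoir neurons receive every (scaled) input channel: a dense
#' `nReservoir x nInputs` matrix with i.i.d. Uniform\[-1, 1\] entries.
#'
#' @param nReservoir number of reservoir neurons
#' @param nInputs number of input channels
#' @param seed integer seed (NULL = current RNG stream)
#' @return numeric matrix W_in
#' @export
initInputWeights <- function(nReservoir, nInputs, seed = NULL) {
  checkScalar(nReservoir, "nReservoir", lower = 1, integer = TRUE)
  checkScalar(nInputs, "nInputs", lower = 1, integer = TRUE)
  withSeed(seed,
    matrix(runif(nReservoir * nInputs, -1, 1), nReservoir, nInputs))
}

#' Drive the reservoir with an input series
#'
#' Runs the leaky-neuron recursion
#' `r'(t) = f(W_in (epsilon x(t)) + W r(t-1) + b)`,
#' `r(t) = alpha r'(t) + (1 - alpha) r(t-1)` from `r(0) = 0` (or `r0`)
#' and returns all states. With `f = tanh` every state entry lies in
#' \[-1, 1\].
#'
#' @param x T x Nx input matrix (or vector for a single channel), unscaled
#' @param W reservoir weights: a [ReservoirMatrix-class] (typically after
#'   [scaleSpectralRadius()]) or a plain square matrix
#' @param Win `Nr x Nx` input weight matrix (see [initInputWeights()])
#' @param config an [ESNConfig-class]
#' @param r0 optional initial state (defaults to zeros; non-default values
#'   are used by echo-state-property diagnostics)
#' @return a [StateTrajectory-class]
#' @export
runReservoir <- function(x, W, Win, config = esnConfig(), r0 = NULL) {
  x <- asInputMatrix(x)
  Wm <- if (is(W, "ReservoirMatrix")) weightMatrix(W) else W
  if (!is.matrix(Wm) || nrow(Wm) != ncol(Wm))
    validationError("`W` must be a square matrix or ReservoirMatrix")
  nr <- nrow(Wm)
  if (!is.matrix(Win) || nrow(Win) != nr || ncol(Win) != ncol(x))
    validationError(sprintf(
      "`Win` must be %d x %d to match the reservoir and input", nr, ncol(x)))
  if (is.null(r0)) r0 <- numeric(nr)
  if (length(r0) != nr) validationError("`r0` length must equal Nr")
  states <- reservoir_states_cpp(
    config@inputScaling * x, Wm, Win,
    config@leakage, config@bias, as.numeric(r0),
    config@leakIntegration == "printed",
    config@reservoirActivation == "identity")
  new("StateTrajectory", states = states, inputs = x)
}

# Minimum-norm least squares via rank-revealing pseudoinverse: singular
# values below max(dim) * eps * sigma_max are treated as zero.
pinvSolve <- function(Z, Y) {
  sv <- svd(Z)
  tol <- max(dim(Z)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  if (!any(pos)) return(matrix(0, ncol(Z), ncol(Y)))
  sv$v[, pos, drop = FALSE] %*%
    (crossprod(sv$u[, pos, drop = FALSE], Y) / sv$d[pos])
}

#' Fit the linear readout by pseudoinverse regression
#'
#' Solves `W_out = Z^+ Y` where `Z = [x(t); r(t)]` concatenates the
#' (unscaled) inputs with the reservoir states and `Z^+` is the
#' rank-revealing Moore-Penrose pseudoinverse: among all Frobenius-residual
#' minimizers the minimum-norm one. The first `transient` steps are
#' discarded, as are steps whose target contains NA (undefined leading lag
#' entries).
#'
#' @param x T x Nx input matrix (or vector), unscaled
#' @param states T x Nr state matrix (from [runReservoir()])
#' @param y T x Ny target matrix (or vector); NA rows are dropped
#' @param config an [ESNConfig-class] (supplies `transient` and the output
#'   activation)
#' @return a [Readout-class]
#' @export
fitReadout <- function(x, states, y, config = esnConfig()) {
  x <- asInputMatrix(x)
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  if (nrow(x) != nrow(states) || nrow(x) != nrow(y))
    validationError("x, states and y must have the same number of rows")
  tr <- config@transient
  if (nrow(x) <= tr)
    degenerateError(sprintf(
      "series length %d does not exceed the transient %d", nrow(x), tr))
  keep <- seq_len(nrow(x)) > tr & !apply(y, 1, anyNA)
  Z <- cbind(x, states)[keep, , drop = FALSE]
  Y <- y[keep, , drop = FALSE]
  if (any(!is.finite(Y))) validationError("targets must be finite")
  B <- pinvSolve(Z, Y)
  new("Readout", weights = t(B),
      outputActivation = config@outputActivation,
      nInputs = ncol(x))
}

#' Predict outputs from a trained readout
#'
#' `y_hat(t) = g(W_out [x(t); r(t)])` with `g` the identity or ReLU.
#'
#' @param x T x Nx input matrix (or vector), unscaled
#' @param states T x Nr state matrix
#' @param readout a [Readout-class]
#' @return T x Ny prediction matrix
#' @export
predictOutput <- function(x, states, readout) {
  x <- asInputMatrix(x)
  if (ncol(x) != readout@nInputs)
    validationError("input channel count does not match the readout")
  Z <- cbind(x, states)
  if (ncol(Z) != ncol(readout@weights))
    validationError("state dimension does not match the readout")
  yhat <- Z %*% t(readout@weights)
  if (readout@outputActivation == "relu") yhat <- pmax(yhat, 0)
  yhat
}
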