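#' Area-level connectome
#'
#' A weighted, directed, non-negative area-by-area connectivity matrix.
#' Entry `[i, j]` is the projection strength from source area `i` to target
#' area `j`; the diagonal (area-level self-projections) is zero by
#' construction.
#'
#' @slot weights square numeric matrix, finite, elementwise >= 0, zero
#'   diagonal.
#' @slot labels character vector of area names, one per row/column.
#'
#' @seealso [readConnectome()], [synthConnectome()], [upscaleConnectome()]
#' @exportClass Connectome
setClass("Connectome",
  representation(weights = "matrix", labels = "character"))

setValidity("Connectome", function(object) {
  w <- object@weights
  if (!is.numeric(w)) return("weights must be numeric")
  if (nrow(w) != ncol(w)) return("weights must be a square matrix")
  if (any(!is.finite(w))) return("weights must be finite")
  if (any(w < 0)) return("weights must be non-negative")
  if (any(diag(w) != 0)) return("diagonal (self-projections) must be zero")
  if (length(object@labels) != nrow(w))
    return("labels length must equal the matrix dimension")
  TRUE
})

#' Neuron-level connectome produced by upscaling
#'
#' An area-level [Connectome-class] mapped onto `nAreas * neuronsPerArea`
#' neurons. Every empirical interareal link becomes a fully connected
#' neuron-level block whose entries sum to the empirical weight; within-area
#' (intrinsic) blocks carry a fixed fraction of each area's extrinsic
#' weight budget.
#'
#' @slot areaOfNeuron integer vector mapping neuron index to source area.
#' @slot neuronsPerArea scaling factor (neurons per area).
#' @slot interarealMode `"homogeneous"` (equal partition of block totals)
#'   or `"heterogeneous"` (random proportions).
#' @slot intrinsicRatio ratio of intrinsic (within-area) to extrinsic
#'   (between-area) total strength per area.
#' @slot intraConnFraction fraction of realizable within-area neuron pairs
#'   that are formed.
#' @slot sourceMask binary area-level mask of the source connectome.
#' @slot sourceLabels area labels of the source connectome.
#'
#' @exportClass UpscaledConnectome
setClass("UpscaledConnectome",
  contains = "Connectome",
  representation(
    areaOfNeuron = "integer",
    neuronsPerArea = "integer",
    interarealMode = "character",
    intrinsicRatio = "numeric",
    intraConnFraction = "numeric",
    sourceMask = "matrix",
    sourceLabels = "character"))

setValidity("UpscaledConnectome", function(object) {
  if (length(object@areaOfNeuron) != nrow(object@weights))
    return("areaOfNeuron must map every neuron")
  if (object@neuronsPerArea < 1L) return("neuronsPerArea must be >= 1")
  if (!object@interarealMode %in% c("homogeneous", "heterogeneous"))
    return("interarealMode must be homogeneous or heterogeneous")
  TRUE
})

#' Reservoir weight matrix under a connectivity condition
#'
#' Signed neuron-level weights for an echo state network reservoir. Weights
#' are nonzero exactly where `mask` is 1; before spectral scaling all
#' weights lie in \[-1, 1\] (uniform draws); after [scaleSpectralRadius()]
#' the `spectralRadius` slot records the imposed radius.
#'
#' @slot weights square signed numeric matrix.
#' @slot mask 0/1 matrix marking existing links; zero diagonal.
#' @slot condition one of `"bio-rank"`, `"bio-no-rank"`, `"random-density"`,
#'   `"random-k"`, `"random-full"`.
#' @slot seed integer seed the condition was generated under (NA if the
#'   ambient RNG stream was used).
#' @slot areaOfNeuron optional neuron-to-area map (present for reservoirs
#'   built from upscaled connectomes; otherwise length 0).
#' @slot spectralRadius imposed spectral radius, NA before scaling.
#'
#' @exportClass ReservoirMatrix
setClass("ReservoirMatrix",
  representation(
    weights = "matrix",
    mask = "matrix",
    condition = "character",
    seed = "integer",
    areaOfNeuron = "integer",
    spectralRadius = "numeric"))

setValidity("ReservoirMatrix", function(object) {
  w <- object@weights; m <- object@mask
  if (!all(dim(w) == dim(m))) return("weights and mask dimensions differ")
  if (nrow(w) != ncol(w)) return("weights must be square")
  if (any(!m %in% c(0, 1))) return("mask must be 0/1")
  if (any(diag(m) != 0)) return("mask diagonal must be zero")
  if (any((w != 0) != (m == 1)))
    return("weights must be nonzero exactly where mask == 1")
  TRUE
})

#' Echo state network hyperparameters
#'
#' Houses the reservoir hyperparameters: spectral radius rho, input scaling
#' epsilon, leakage rate alpha, bias b, the reservoir and output activation
#' functions, and the transient (washout) length discarded from training and
#' test. Defaults are the fixed post-tuning constellation used for all main
#' experiments: rho = 0.99, epsilon = 1e-5, alpha = 1, b = 1, tanh
#' reservoir, transient 100.
#'
#' @slot spectralRadius target spectral radius rho (> 0).
#' @slot inputScaling input scaling factor epsilon applied to x(t) before
#'   the input weights.
#' @slot leakage leakage rate alpha in (0, 1]; alpha = 1 means no leakage.
#' @slot bias scalar bias b, broadcast to the bias vector.
#' @slot reservoirActivation `"tanh"` (or `"identity"`, a diagnostic mode
#'   used by linear-reservoir oracles).
#' @slot outputActivation `"identity"` or `"relu"`.
#' @slot transient initial steps discarded from fitting and scoring.
#' @slot seed provenance seed (NA when unset).
#' @slot leakIntegration `"standard"` for
#'   `r(t) = alpha*r'(t) + (1-alpha)*r(t-1)`; `"printed"` for the variant
#'   with an extra recurrent multiplication in the leak term,
#'   `r(t) = alpha*r'(t) + (1-alpha)*W r(t-1)`. Identical when alpha = 1.
#'
#' @seealso [esnConfig()]
#' @exportClass ESNConfig
setClass("ESNConfig",
  representation(
    spectralRadius = "numeric",
    inputScaling = "numeric",
    leakage = "numeric",
    bias = "numeric",
    reservoirActivation = "character",
    outputActivation = "character",
    transient = "integer",
    seed = "integer",
    leakIntegration = "character"))

setValidity("ESNConfig", function(object) {
  if (object@spectralRadius <= 0) return("spectralRadius must be > 0")
  if (object@leakage <= 0 || object@leakage > 1)
    return("leakage must be in (0, 1]")
  if (object@transient < 0L) return("transient must be >= 0")
  if (!object@reservoirActivation %in% c("tanh", "identity"))
    return("reservoirActivation must be tanh or identity")
  if (!object@outputActivation %in% c("identity", "relu"))
    return("outputActivation must be identity or relu")
  if (!object@leakIntegration %in% c("standard", "printed"))
    return("leakIntegration must be standard or printed")
  TRUE
})

#' Reservoir state trajectory
#'
#' @slot states T x Nr matrix of reservoir activations r(t); bounded in
#'   \[-1, 1\] under the tanh activation.
#' @slot inputs T x Nx matrix of the (unscaled) driving inputs x(t).
#' @exportClass StateTrajectory
setClass("StateTrajectory",
  representation(states = "matrix", inputs = "matrix"))

setValidity("StateTrajectory", function(object) {
  if (nrow(object@states) != nrow(object@inputs))
    return("states and inputs must cover the same time steps")
  TRUE
})

#' Trained linear readout
#'
#' @slot weights Ny x (Nx + Nr) readout matrix W_out acting on the vertical
#'   concatenation \[x(t); r(t)\].
#' @slot outputActivation `"identity"` or `"relu"`.
#' @slot nInputs number of input channels Nx (to validate concatenation).
#' @exportClass Readout
setClass("Readout",
  representation(weights = "matrix", outputActivation = "character",
                 nInputs = "integer"))

#' Memory Capacity task data
#'
#' Input series x(t) ~ Uniform(-0.5, 0.5) and lagged targets
#' `y[t, k] = x[t - lags[k]]`. Leading entries with `t <= lag` are NA and
#' excluded from fitting and scoring.
#'
#' @slot x T x 1 input matrix.
#' @slot y T x n_lags target matrix (NA where undefined).
#' @slot lags strictly increasing positive integer lags.
#' @exportClass MemoryCapacityData
setClass("MemoryCapacityData",
  representation(x = "matrix", y = "matrix", lags = "integer"))

#' Sequence Recall task data
#'
#' Trials of `fixationLen` fixation steps (cue x2 = 0, random x1 in (0,1),
#' target 0) followed by `patternLength` recall steps (cue x2 = 1, x1 = 0,
#' target = the last `patternLength` fixation inputs in order), concatenated
#' into one continuous series.
#'
#' @slot x T x 2 input matrix with columns x1 (sequence) and x2 (cue).
#' @slot y T x 1 target matrix.
#' @slot patternLength pattern length L (task difficulty).
#' @slot fixationLen fixation steps per trial (>= L).
#' @slot trials data.frame with columns fixationStart, recallStart,
#'   trialEnd (1-based step indices).
#' @exportClass SequenceRecallData
setClass("SequenceRecallData",
  representation(x = "matrix", y = "matrix", patternLength = "integer",
                 fixationLen = "integer", trials = "data.frame"))

#' Task evaluation result
#'
#' Per-output scores and the aggregate: for Memory Capacity the per-lag
#' squared Pearson correlations and their sum MC; for Sequence Recall the
#' pooled R^2 over recall steps.
#'
#' @slot perOutput numeric vector of per-output scores.
#' @slot aggregate the aggregate score (MC or recall R^2).
#' @slot nScored number of scored time steps.
#' @slot task `"memory-capacity"` or `"sequence-recall"`.
#' @slot info provenance list (condition, seed, size, ...).
#' @exportClass EvalResult
setClass("EvalResult",
  representation(perOutput = "numeric", aggregate = "numeric",
                 nScored = "integer", task = "character", info = "list"))

#' Experiment plan
#'
#' Describes a replicate sweep: which connectome, which connectivity
#' conditions, which task and difficulties, how many replicate networks,
#' which upscaling sizes, and the base seed from which every
#' (condition, size, replicate) cell derives its own reproducible seed.
#'
#' @slot connectome the source [Connectome-class].
#' @slot conditions subset of the five condition names.
#' @slot task `"memory-capacity"` or `"sequence-recall"`.
#' @slot config [ESNConfig-class] used for every cell.
#' @slot nReplicates replicate networks per cell (>= 1).
#' @slot sizes neurons-per-area scaling factors (1 = no upscaling).
#' @slot interarealMode upscaling mode for sizes > 1.
#' @slot lags Memory Capacity lag set.
#' @slot patternLengths Sequence Recall difficulties L.
#' @slot tTrain,tTest Memory Capacity split sizes (time steps).
#' @slot nTrainTrials,nTestTrials Sequence Recall split sizes (trials).
#' @slot fixationLen fixation steps per trial (NA = patternLength).
#' @slot k fan-in for the random-k condition.
#' @slot baseSeed base seed of the sweep.
#' @seealso [experimentPlan()], [runReplicates()]
#' @exportClass ExperimentPlan
setClass("ExperimentPlan",
  representation(
    connectome = "Connectome",
    conditions = "character",
    task = "character",
    config = "ESNConfig",
    nReplicates = "integer",
    sizes = "integer",
    interarealMode = "character",
    lags = "integer",
    patternLengths = "integer",
    tTrain = "integer",
    tTest = "integer",
    nTrainTrials = "integer",
    nTestTrials = "integer",
    fixationLen = "integer",
    k = "integer",
    baseSeed = "integer"))

setValidity("ExperimentPlan", function(object) {
  bad <- setdiff(object@conditions, reservoirConditions())
  if (length(bad))
    return(sprintf("unknown condition(s): %s (valid: %s)",
                   paste(bad, collapse = ", "),
                   paste(reservoirConditions(), collapse = ", ")))
  if (!object@task %in% c("memory-capacity", "sequence-recall"))
    return("task must be memory-capacity or sequence-recall")
  if (object@nReplicates < 1L) return("nReplicates must be >= 1")
  if (any(object@sizes < 1L)) return("sizes must be >= 1")
  TRUE
})
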