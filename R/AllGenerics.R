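#' @name bioesn-accessors
#' @title Accessors for bioesn objects
#' @description Slot access goes through these accessors, never through
#'   `@`. `weightMatrix` returns the numeric matrix of a connectome or
#'   reservoir; `linkMask` its 0/1 link mask; `nLinks` the number of
#'   directed links; `linkDensity` the fraction of realized off-diagonal
#'   ordered pairs; `areaLabels` the area (or neuron) names;
#'   `areaOfNeuron` the neuron-to-area map of upscaled objects;
#'   `neuronsPerArea` the scaling factor; `conditionName` the surrogate
#'   condition of a reservoir; `spectralRadius` the largest absolute
#'   eigenvalue.
#' @param x a bioesn object
NULL

#' @rdname bioesn-accessors
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname bioesn-accessors
#' @export
setGeneric("linkMask", function(x) standardGeneric("linkMask"))

#' @rdname bioesn-accessors
#' @export
setGeneric("nLinks", function(x) standardGeneric("nLinks"))

#' @rdname bioesn-accessors
#' @export
setGeneric("linkDensity", function(x) standardGeneric("linkDensity"))

#' @rdname bioesn-accessors
#' @export
setGeneric("nAreas", function(x) standardGeneric("nAreas"))

#' @rdname bioesn-accessors
#' @export
setGeneric("areaLabels", function(x) standardGeneric("areaLabels"))

#' @rdname bioesn-accessors
#' @export
setGeneric("areaOfNeuron", function(x) standardGeneric("areaOfNeuron"))

#' @rdname bioesn-accessors
#' @export
setGeneric("neuronsPerArea", function(x) standardGeneric("neuronsPerArea"))

#' @rdname bioesn-accessors
#' @export
setGeneric("conditionName", function(x) standardGeneric("conditionName"))

#' @rdname bioesn-accessors
#' @export
setGeneric("spectralRadius", function(x) standardGeneric("spectralRadius"))

#' Area-level mask of an upscaled connectome
#'
#' Entry (i, j), i != j, is 1 iff any neuron of area i connects to any
#' neuron of area j. For a valid upscaling this equals the binary mask of
#' the source connectome (interareal blocks are all-or-nothing).
#'
#' @param x an [UpscaledConnectome-class]
#' @return binary area-by-area matrix
#' @export
setGeneric("areaMask", function(x) standardGeneric("areaMask"))

#' Rescale reservoir weights to a target spectral radius
#'
#' Multiplies the weights by `rho / max(abs(eigenvalues))` so the resulting
#' spectral radius equals `rho`. The link mask is unchanged. A matrix whose
#' spectral radius is 0 (e.g. nilpotent, such as strictly triangular
#' wiring) cannot be scaled this way and raises a degenerate-input error.
#'
#' @param x a [ReservoirMatrix-class] or plain square matrix
#' @param rho target spectral radius (default 0.99, the fixed post-tuning
#'   value used for all main experiments)
#' @return object of the same class with rescaled weights
#' @export
setGeneric("scaleSpectralRadius",
           function(x, rho = 0.99) standardGeneric("scaleSpectralRadius"))

#' Write a connectome to disk
#'
#' @param x a [Connectome-class]
#' @param path output file path
#' @param format `"delimited"` (text matrix, 17 significant digits, header
#'   row of labels, '#'-comment friendly) or `"binary"` (R serialization of
#'   the weights and labels)
#' @return invisibly, `path`
#' @seealso [readConnectome()]
#' @export
setGeneric("writeConnectome",
  function(x, path, format = c("delimited", "binary"))
    standardGeneric("writeConnectome"))
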