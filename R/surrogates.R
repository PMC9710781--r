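#' Names of the reservoir connectivity conditions
#'
#' The five conditions compared throughout: `bio-rank` and `bio-no-rank`
#' keep the empirical binary topology (who connects to whom), with and
#' without preserving the rank order of connection strengths; the three
#' random controls use a completely random wiring diagram constrained to
#' the empirical density (`random-density`), to a fixed fan-in of k links
#' per neuron (`random-k`), or to full connectivity (`random-full`).
#'
#' @return character vector of valid condition names
#' @export
reservoirConditions <- function() {
  c("bio-rank", "bio-no-rank", "random-density", "random-k", "random-full")
}

#' Sample reservoir link weights
#'
#' i.i.d. Uniform\[-1, 1\] draws, the classical ESN weight distribution.
#' Exact zeros are resampled so that every existing link carries a nonzero
#' weight (the link mask stays recoverable from the weights).
#'
#' @param nLinks number of weights (>= 0)
#' @param seed integer seed (NULL = current RNG stream)
#' @return numeric vector of length `nLinks`, entries in \[-1, 1\], no zeros
#' @export
sampleLinkWeights <- function(nLinks, seed = NULL) {
  checkScalar(nLinks, "nLinks", lower = 0, integer = TRUE)
  withSeed(seed, {
    w <- runif(nLinks, -1, 1)
    while (any(w == 0)) w[w == 0] <- runif(sum(w == 0), -1, 1)
    w
  })
}

# links of a mask ordered by (source, target) index
linkIndex <- function(mask) {
  ind <- which(mask != 0, arr.ind = TRUE)
  ind[order(ind[, 1], ind[, 2]), , drop = FALSE]
}

newReservoir <- function(weights, condition, seed, areaOfNeuron = integer(0)) {
  new("ReservoirMatrix",
      weights = weights, mask = (weights != 0) * 1,
      condition = condition,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      areaOfNeuron = as.integer(areaOfNeuron),
      spectralRadius = NA_real_)
}

reservoirSize <- function(x) {
  if (is(x, "Connectome")) nrow(weightMatrix(x))
  else if (is.matrix(x)) nrow(x)
  else validationError("expected a Connectome or a matrix")
}

#' Rank-preserving biological reservoir (Bio rank)
#'
#' Keeps the empirical topology and places freshly sampled Uniform\[-1, 1\]
#' weights so that their rank order matches the empirical strengths: the
#' strongest empirical link receives the largest (most positive) sampled
#' weight and the weakest link the most negative one. Ties in empirical
#' strength are broken deterministically by (source, target) index order.
#'
#' For an [UpscaledConnectome-class], `rankBy = "neuron"` (default) ranks
#' against the upscaled neuron-level weights; `rankBy = "area"` ranks
#' against the area-level weight of each link's block.
#'
#' @param x a [Connectome-class] (or [UpscaledConnectome-class]) with at
#'   least one link
#' @param seed integer seed (NULL = current RNG stream)
#' @param rankBy reference weights for upscaled inputs (see above)
#' @return a [ReservoirMatrix-class], condition `"bio-rank"`
#' @export
makeBioRank <- function(x, seed = NULL, rankBy = c("neuron", "area")) {
  rankBy <- match.arg(rankBy)
  w <- weightMatrix(x)
  ind <- linkIndex(w)
  n <- nrow(ind)
  if (n < 1) degenerateError("connectome has no links")
  keys <- w[ind]
  if (rankBy == "area" && is(x, "UpscaledConnectome")) {
    a <- areaOfNeuron(x)
    wa <- matrix(0, max(a), max(a))
    src <- weightMatrix(x)
    # area-level key: total block weight (ties within a block resolved by
    # the deterministic index order below)
    for (r in seq_len(n)) {
      i <- a[ind[r, 1]]; j <- a[ind[r, 2]]
      if (wa[i, j] == 0) {
        ni <- which(a == i); nj <- which(a == j)
        wa[i, j] <- sum(src[ni, nj])
      }
      keys[r] <- wa[i, j]
    }
  }
  s <- sampleLinkWeights(n, seed)
  out <- matrix(0, nrow(w), ncol(w))
  # ind is (source, target)-sorted; stable order() keeps that order on ties
  out[ind[order(keys), , drop = FALSE]] <- sort(s)
  newReservoir(out, "bio-rank", seed,
               if (is(x, "UpscaledConnectome")) areaOfNeuron(x) else integer(0))
}

#' Rank-free biological reservoir (Bio no-rank)
#'
#' Keeps the empirical topology but places sampled Uniform\[-1, 1\] weights
#' on the links in a uniformly random permutation, so no rank order is
#' preserved.
#'
#' @inheritParams makeBioRank
#' @return a [ReservoirMatrix-class], condition `"bio-no-rank"`
#' @export
makeBioNoRank <- function(x, seed = NULL) {
  w <- weightMatrix(x)
  ind <- linkIndex(w)
  n <- nrow(ind)
  if (n < 1) degenerateError("connectome has no links")
  out <- matrix(0, nrow(w), ncol(w))
  withSeed(seed, {
    s <- sampleLinkWeights(n)
    perm <- if (n > 1) sample.int(n) else 1L
    out[ind] <- s[perm]
  })
  newReservoir(out, "bio-no-rank", seed,
               if (is(x, "UpscaledConnectome")) areaOfNeuron(x) else integer(0))
}

#' Random reservoir matched to the empirical density
#'
#' Completely random wiring diagram with exactly as many links as the
#' source connectome: link positions are drawn uniformly without
#' replacement from the off-diagonal ordered pairs.
#'
#' @inheritParams makeBioRank
#' @return a [ReservoirMatrix-class], condition `"random-density"`
#' @export
makeRandomDensity <- function(x, seed = NULL) {
  n <- reservoirSize(x)
  m <- nLinks(x)
  offdiag <- which(row(matrix(0, n, n)) != col(matrix(0, n, n)))
  out <- matrix(0, n, n)
  withSeed(seed, {
    pos <- sample(offdiag, m)
    out[pos] <- sampleLinkWeights(m)
  })
  newReservoir(out, "random-density", seed)
}

#' Random reservoir with fixed fan-in k
#'
#' Completely random wiring with a fixed number of connections per neuron:
#' each neuron receives exactly `k` incoming links chosen uniformly among
#' the other `n - 1` neurons (classical sparse-ESN wiring; all main
#' experiments use k = 10). `degree = "out"` fixes the out-degree instead.
#'
#' @param n reservoir size
#' @param k links per neuron (1 <= k <= n - 1)
#' @param seed integer seed (NULL = current RNG stream)
#' @param degree `"in"` (fan-in, default) or `"out"` (fan-out)
#' @return a [ReservoirMatrix-class], condition `"random-k"`, with
#'   `n * k` links
#' @export
makeRandomK <- function(n, k = 10, seed = NULL, degree = c("in", "out")) {
  degree <- match.arg(degree)
  checkScalar(n, "n", lower = 2, integer = TRUE)
  checkScalar(k, "k", lower = 1, integer = TRUE)
  if (k > n - 1)
    degenerateError(sprintf("k = %d exceeds the maximum degree n - 1 = %d",
                            k, n - 1))
  out <- matrix(0, n, n)
  withSeed(seed, {
    for (j in seq_len(n)) {
      partners <- sample(setdiff(seq_len(n), j), k)
      if (degree == "in") out[partners, j] <- sampleLinkWeights(k)
      else out[j, partners] <- sampleLinkWeights(k)
    }
  })
  newReservoir(out, "random-k", seed)
}

#' Fully connected random reservoir
#'
#' No wiring restrictions: all `n(n-1)` off-diagonal links are present
#' (density 1), weights sampled Uniform\[-1, 1\].
#'
#' @param n reservoir size (>= 2)
#' @param seed integer seed (NULL = current RNG stream)
#' @return a [ReservoirMatrix-class], condition `"random-full"`
#' @export
makeRandomFull <- function(n, seed = NULL) {
  checkScalar(n, "n", lower = 2, integer = TRUE)
  if (n < 2) degenerateError("need n >= 2")
  out <- matrix(0, n, n)
  offdiag <- which(row(out) != col(out))
  withSeed(seed, out[offdiag] <- sampleLinkWeights(length(offdiag)))
  newReservoir(out, "random-full", seed)
}

#' Build a reservoir under a named connectivity condition
#'
#' Dispatcher over the five conditions; `x` supplies the topology for the
#' biological conditions, the link count for `random-density`, and the
#' reservoir size for `random-k` / `random-full`.
#'
#' @param x a [Connectome-class] or [UpscaledConnectome-class]
#' @param condition one of [reservoirConditions()]
#' @param seed integer seed (NULL = current RNG stream)
#' @param k fan-in for `random-k` (default 10)
#' @param ... further arguments to the specific constructor (e.g. `rankBy`,
#'   `degree`)
#' @return a [ReservoirMatrix-class]
#' @export
makeReservoir <- function(x, condition, seed = NULL, k = 10, ...) {
  if (!condition %in% reservoirConditions())
    validationError(sprintf("unknown condition '%s'; valid: %s", condition,
                            paste(reservoirConditions(), collapse = ", ")))
  switch(condition,
    "bio-rank"       = makeBioRank(x, seed, ...),
    "bio-no-rank"    = makeBioNoRank(x, seed),
    "random-density" = makeRandomDensity(x, seed),
    "random-k"       = makeRandomK(reservoirSize(x), k, seed, ...),
    "random-full"    = makeRandomFull(reservoirSize(x), seed))
}

#' @rdname bioesn-accessors
setMethod("weightMatrix", "ReservoirMatrix", function(x) x@weights)

#' @rdname bioesn-accessors
setMethod("linkMask", "ReservoirMatrix", function(x) x@mask)

#' @rdname bioesn-accessors
setMethod("nLinks", "ReservoirMatrix", function(x) sum(x@mask))

#' @rdname bioesn-accessors
setMethod("linkDensity", "ReservoirMatrix", function(x) {
  n <- nrow(x@mask)
  sum(x@mask) / (n * (n - 1))
})

#' @rdname bioesn-accessors
setMethod("conditionName", "ReservoirMatrix", function(x) x@condition)

#' @rdname bioesn-accessors
setMethod("areaOfNeuron", "ReservoirMatrix", function(x) x@areaOfNeuron)

#' @rdname bioesn-accessors
setMethod("spectralRadius", "ReservoirMatrix",
          function(x) spectralRadius(x@weights))

#' @rdname bioesn-accessors
setMethod("spectralRadius", "matrix",
          function(x) max(abs(eigen(x, only.values = TRUE)$values)))

setMethod("show", "ReservoirMatrix", function(object) {
  cat(sprintf(
    "ReservoirMatrix: %d neurons, %d links, condition '%s'%s\n",
    nrow(object@weights), nLinks(object), object@condition,
    if (is.na(object@spectralRadius)) " (unscaled)"
    else sprintf(", spectral radius %.4g", object@spectralRadius)))
})

# Nilpotent matrices (e.g. strictly triangular wiring) have true spectral
# radius 0 even though eigen() reports O(eps^(1/n)) noise; detect them by
# repeated squaring, which reaches the exact zero matrix in log2(n) steps.
isNilpotent <- function(x) {
  if (all(x == 0)) return(TRUE)
  p <- x
  for (i in seq_len(ceiling(log2(nrow(x))) + 1L)) {
    p <- p %*% p
    if (all(p == 0)) return(TRUE)
    p <- p / max(abs(p)) # guard overflow/underflow
  }
  FALSE
}

#' @rdname scaleSpectralRadius
setMethod("scaleSpectralRadius", "matrix", function(x, rho = 0.99) {
  checkScalar(rho, "rho", lower = .Machine$double.xmin)
  if (isNilpotent(x))
    degenerateError(paste(
      "spectral radius is 0 (nilpotent or empty wiring);",
      "such a matrix cannot be rescaled to a target radius -",
      "add cycles or use a different condition"))
  x * (rho / spectralRadius(x))
})

#' @rdname scaleSpectralRadius
setMethod("scaleSpectralRadius", "ReservoirMatrix", function(x, rho = 0.99) {
  x@weights <- scaleSpectralRadius(x@weights, rho)
  x@spectralRadius <- rho
  validObject(x)
  x
})
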