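#' Upscale an area-level connectome to a neuron-level network
#'
#' Maps each area onto `neuronsPerArea` neurons while preserving the
#' area-level wiring diagram and conserving interareal weight totals. For
#' every empirical link (i, j) all `neuronsPerArea^2` neuron pairs between
#' the two populations are connected and the empirical weight `w[i, j]` is
#' partitioned across them: in `homogeneous` mode in equal parts, in
#' `heterogeneous` mode by random proportions drawn from a symmetric
#' Dirichlet distribution with concentration `concentration`. Empirical
#' non-links stay empty blocks, so the area-level mask is preserved
#' exactly.
#'
#' The default `concentration = 0.1` gives a strongly skewed random
#' partition - a few neuron pairs carry most of each block's weight -
#' which mirrors the sparse, heavy-tailed way axonal projections allocate
#' synaptic weight at neuron level. Large concentrations approach the
#' homogeneous split; `concentration = 1` is the flat Dirichlet.
#'
#' Within-area (intrinsic) connectivity follows an empirical rule: each
#' area's total intrinsic strength is `intrinsicRatio` times its total
#' extrinsic between-area strength (default 0.8, i.e. intrinsic = 80% of
#' extrinsic). A fraction `intraConnFraction` of the
#' `neuronsPerArea * (neuronsPerArea - 1)` realizable within-area pairs is
#' formed (default 1: all of them, no self-loops), and the intrinsic total
#' is partitioned over the formed pairs in the same mode as the interareal
#' blocks. With `neuronsPerArea = 1` there are no realizable intrinsic
#' pairs and the result equals the source connectome.
#'
#' @param x a [Connectome-class]
#' @param neuronsPerArea scaling factor (>= 1); reservoir size becomes
#'   `nAreas(x) * neuronsPerArea`
#' @param interarealMode `"homogeneous"` or `"heterogeneous"`
#' @param intrinsicRatio intrinsic-to-extrinsic strength ratio per area
#'   (>= 0, default 0.8)
#' @param intraConnFraction fraction of realizable within-area pairs formed
#'   (in (0, 1], default 1)
#' @param extrinsicBasis which extrinsic budget defines an area's intrinsic
#'   total: `"out"` (total outgoing interareal weight, default) or `"in"`
#' @param concentration Dirichlet concentration of the heterogeneous
#'   partition (> 0; ignored in homogeneous mode)
#' @param seed integer seed (NULL = current RNG stream); only consumed in
#'   heterogeneous mode or when `intraConnFraction < 1`
#' @return an [UpscaledConnectome-class]
#' @examples
#' con <- synthConnectome(10, nModules = 2, density = 0.3, seed = 7)
#' up <- upscaleConnectome(con, 5, "heterogeneous", seed = 7)
#' nAreas(up) # 50 neurons
#' @export
upscaleConnectome <- function(x, neuronsPerArea,
                              interarealMode = c("homogeneous",
                                                 "heterogeneous"),
                              intrinsicRatio = 0.8, intraConnFraction = 1,
                              extrinsicBasis = c("out", "in"),
                              concentration = 0.1, seed = NULL) {
  interarealMode <- match.arg(interarealMode)
  extrinsicBasis <- match.arg(extrinsicBasis)
  if (!is(x, "Connectome")) validationError("`x` must be a Connectome")
  checkScalar(neuronsPerArea, "neuronsPerArea", lower = 1, integer = TRUE)
  if (intrinsicRatio < 0) validationError("`intrinsicRatio` must be >= 0")
  checkScalar(intraConnFraction, "intraConnFraction",
              lower = .Machine$double.xmin, upper = 1)
  checkScalar(concentration, "concentration", lower = .Machine$double.xmin)
  # strictly positive Dirichlet proportions (resample underflow zeros so
  # every formed pair carries weight)
  rdirichlet <- function(m) {
    g <- rgamma(m, shape = concentration)
    while (any(g == 0)) g[g == 0] <- rgamma(sum(g == 0), shape = concentration)
    g / sum(g)
  }
  npa <- as.integer(neuronsPerArea)
  w <- weightMatrix(x)
  n <- nrow(w)
  nr <- n * npa
  big <- matrix(0, nr, nr)
  areaOf <- rep(seq_len(n), each = npa)
  block <- function(i) ((i - 1L) * npa + 1L):(i * npa)
  homog <- interarealMode == "homogeneous"
  withSeed(seed, {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || w[i, j] == 0) next
      if (homog) {
        big[block(i), block(j)] <- w[i, j] / npa^2
      } else {
        big[block(i), block(j)] <- w[i, j] * rdirichlet(npa^2)
      }
    }
    if (npa > 1L && intrinsicRatio > 0) {
      ext <- if (extrinsicBasis == "out") rowSums(w) else colSums(w)
      for (i in seq_len(n)) {
        if (ext[i] == 0) next
        total <- intrinsicRatio * ext[i]
        sub <- matrix(0, npa, npa)
        pairs <- which(row(sub) != col(sub)) # realizable: no self-loops
        m <- round(intraConnFraction * length(pairs))
        if (m < 1) {
          warning(sprintf(
            "area %d: intraConnFraction too small, no intrinsic pairs formed",
            i), call. = FALSE)
          next
        }
        formed <- if (m < length(pairs)) sample(pairs, m) else pairs
        if (homog) sub[formed] <- total / m
        else sub[formed] <- total * rdirichlet(m)
        big[block(i), block(i)] <- sub
      }
    }
  })
  labels <- paste0(rep(areaLabels(x), each = npa), "_n",
                   rep(seq_len(npa), n))
  new("UpscaledConnectome",
      weights = big, labels = labels,
      areaOfNeuron = areaOf, neuronsPerArea = npa,
      interarealMode = interarealMode,
      intrinsicRatio = intrinsicRatio,
      intraConnFraction = intraConnFraction,
      sourceMask = (w != 0) * 1, sourceLabels = areaLabels(x))
}

#' @rdname bioesn-accessors
setMethod("areaOfNeuron", "UpscaledConnectome", function(x) x@areaOfNeuron)

#' @rdname bioesn-accessors
setMethod("neuronsPerArea", "UpscaledConnectome", function(x) x@neuronsPerArea)

#' @rdname areaMask
setMethod("areaMask", "UpscaledConnectome", function(x) {
  a <- x@areaOfNeuron
  n <- length(x@sourceLabels)
  w <- x@weights
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    out[i, j] <- as.numeric(any(w[a == i, a == j] != 0))
  }
  out
})

setMethod("show", "UpscaledConnectome", function(object) {
  cat(sprintf(
    "UpscaledConnectome: %d areas x %d neurons/area = %d neurons (%s)\n",
    length(object@sourceLabels), object@neuronsPerArea,
    nrow(object@weights), object@interarealMode))
  cat(sprintf("  intrinsic ratio %.3g, intra fraction %.3g, %d links\n",
              object@intrinsicRatio, object@intraConnFraction,
              nLinks(object)))
})
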