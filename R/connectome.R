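#' Construct an area-level connectome
#'
#' Validates a weight matrix as a connectome. Nonzero diagonal entries
#' (area-level self-projections) are zeroed with a warning, matching how
#' real connectivity exports are commonly cleaned on load.
#'
#' @param weights square numeric matrix, finite, elementwise >= 0; rows are
#'   sources, columns are targets
#' @param labels optional character vector of area names; defaults to
#'   `area_0 .. area_{N-1}`
#' @return a [Connectome-class]
#' @examples
#' con <- Connectome(matrix(c(0, 0.6, 0.2, 0), 2, 2, byrow = TRUE))
#' nLinks(con)
#' @export
Connectome <- function(weights, labels = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights))
    formatError("`weights` must be a numeric matrix")
  if (nrow(weights) != ncol(weights))
    formatError(sprintf("`weights` must be square (got %d x %d)",
                        nrow(weights), ncol(weights)))
  if (any(!is.finite(weights)))
    validationError("`weights` contains non-finite entries")
  if (any(weights < 0))
    validationError("`weights` contains negative entries")
  if (any(diag(weights) != 0)) {
    warning("nonzero diagonal entries (self-projections) set to zero",
            call. = FALSE)
    diag(weights) <- 0
  }
  n <- nrow(weights)
  if (is.null(labels)) labels <- paste0("area_", seq_len(n) - 1L)
  if (length(labels) != n)
    validationError("`labels` length must equal the matrix dimension")
  dimnames(weights) <- NULL
  new("Connectome", weights = weights, labels = as.character(labels))
}

#' @rdname bioesn-accessors
setMethod("weightMatrix", "Connectome", function(x) x@weights)

#' @rdname bioesn-accessors
setMethod("linkMask", "Connectome",
          function(x) (x@weights != 0) * 1)

#' @rdname bioesn-accessors
setMethod("nLinks", "Connectome", function(x) sum(x@weights != 0))

#' @rdname bioesn-accessors
setMethod("linkDensity", "Connectome", function(x) {
  n <- nrow(x@weights)
  nLinks(x) / (n * (n - 1))
})

#' @rdname bioesn-accessors
setMethod("nAreas", "Connectome", function(x) nrow(x@weights))

#' @rdname bioesn-accessors
setMethod("areaLabels", "Connectome", function(x) x@labels)

setMethod("show", "Connectome", function(object) {
  n <- nAreas(object)
  cat(sprintf("%s: %d areas, %d directed links (density %.3f)\n",
              class(object), n, nLinks(object), linkDensity(object)))
  w <- object@weights[object@weights > 0]
  if (length(w))
    cat(sprintf("  weights: min %.3g, median %.3g, max %.3g\n",
                min(w), stats::median(w), max(w)))
})

#' Read a connectome from disk
#'
#' The canonical exchange format is a delimited text matrix: comma- or
#' tab-separated, lines starting with `#` ignored, with an optional single
#' header row of area labels. A `binary` container (R serialization of a
#' list with elements `weights` and `labels`) is supported for bit-exact
#' round-tripping.
#'
#' Nonzero diagonal entries are zeroed with a warning; missing labels
#' default to `area_0 .. area_{N-1}`.
#'
#' @param path input file
#' @param format `"auto"` (by extension: `.rds` is binary), `"delimited"`,
#'   or `"binary"`
#' @return a [Connectome-class]
#' @export
readConnectome <- function(path, format = c("auto", "delimited", "binary")) {
  format <- match.arg(format)
  if (!file.exists(path)) ioError(sprintf("file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE))
      "binary" else "delimited"
  if (format == "binary") {
    obj <- readRDS(path)
    if (!is.list(obj) || is.null(obj$weights))
      formatError("binary container must hold elements `weights` (+ `labels`)")
    return(Connectome(obj$weights, obj$labels))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) formatError(sprintf("empty connectome file: %s", path))
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  toks <- lapply(strsplit(lines, sep, fixed = TRUE), trimws)
  first <- suppressWarnings(as.numeric(toks[[1]]))
  labels <- NULL
  if (anyNA(first)) { # header row of labels
    labels <- toks[[1]]
    toks <- toks[-1]
    if (!length(toks)) formatError("file contains only a header row")
  }
  lens <- lengths(toks)
  if (length(unique(lens)) != 1L)
    formatError("ragged rows: all rows must have the same number of fields")
  vals <- suppressWarnings(vapply(toks, as.numeric, numeric(lens[[1]])))
  vals <- if (is.matrix(vals)) t(vals) else matrix(vals, nrow = length(toks))
  if (anyNA(vals)) formatError("non-numeric entry in connectome matrix")
  if (nrow(vals) != ncol(vals))
    formatError(sprintf("non-square matrix: %d rows x %d columns",
                        nrow(vals), ncol(vals)))
  Connectome(vals, labels)
}

# shared low-level text-matrix writer (17 significant digits round-trips
# doubles exactly)
writeDelimitedMatrix <- function(w, path, labels = NULL, sep = ",") {
  rows <- apply(w, 1, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = sep))
  if (!is.null(labels)) rows <- c(paste(labels, collapse = sep), rows)
  ok <- tryCatch({ writeLines(rows, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) ioError(sprintf("cannot write to: %s", path))
  invisible(path)
}

#' @rdname writeConnectome
setMethod("writeConnectome", "Connectome",
  function(x, path, format = c("delimited", "binary")) {
    format <- match.arg(format)
    if (format == "binary") {
      ok <- tryCatch({
        saveRDS(list(weights = x@weights, labels = x@labels), path)
        TRUE
      }, error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok) ioError(sprintf("cannot write to: %s", path))
      return(invisible(path))
    }
    writeDelimitedMatrix(x@weights, path, labels = x@labels)
  })

#' Generate a synthetic modular connectome
#'
#' Stands in for empirical area-level connectomes: a sparse, directed,
#' modular graph with heavy-tailed positive weights and zero diagonal.
#' Areas are split into `nModules` contiguous modules of near-equal size.
#' Intra-module ordered pairs are filled before inter-module pairs, so for
#' densities below the intra-module capacity the graph is purely modular.
#'
#' Link weights are drawn i.i.d. log-normal (meanlog 0, sdlog 1) times
#' `weightScale`, then allocated to emulate two robust statistical
#' properties of real cortical connectomes while keeping the marginal
#' weight distribution exactly log-normal: (i) strength-topology coupling
#' - the largest draws fall on intra-module links (randomly arranged
#' across unordered pairs within each class); and (ii) reciprocal weight
#' correlation - when both directions of an area pair are connected they
#' receive adjacent ranks, hence near-identical strengths. Rank-preserving
#' surrogates are only distinguishable from rank-free ones when such
#' strength-topology structure exists.
#'
#' @param nAreas number of areas (N)
#' @param nModules number of modules (1 <= nModules <= nAreas)
#' @param density fraction of the N(N-1) ordered off-diagonal pairs that
#'   are connected; realized count is `round(density * N * (N-1))`
#' @param weightScale multiplicative scale of the log-normal weights
#' @param seed integer seed (NULL = use the current RNG stream)
#' @return a [Connectome-class]
#' @examples
#' con <- synthConnectome(30, nModules = 3, density = 0.35, seed = 1)
#' linkDensity(con)
#' @export
synthConnectome <- function(nAreas, nModules = 1, density, weightScale = 1,
                            seed = NULL) {
  checkScalar(nAreas, "nAreas", lower = 2, integer = TRUE)
  checkScalar(nModules, "nModules", lower = 1, upper = nAreas, integer = TRUE)
  checkScalar(density, "density", lower = 0, upper = 1)
  checkScalar(weightScale, "weightScale", lower = .Machine$double.xmin)
  nAreas <- as.integer(nAreas); nModules <- as.integer(nModules)
  total <- nAreas * (nAreas - 1)
  nLinks <- round(density * total)
  if (nLinks < 1)
    degenerateError("requested density yields zero links (density * N(N-1) < 1)")
  sizes <- diff(floor(seq(0, nAreas, length.out = nModules + 1)))
  module <- rep(seq_len(nModules), times = sizes)
  src <- rep(seq_len(nAreas), times = nAreas)
  tgt <- rep(seq_len(nAreas), each = nAreas)
  off <- src != tgt
  src <- src[off]; tgt <- tgt[off]
  intra <- module[src] == module[tgt]
  shuffle <- function(v) if (length(v) > 1L) sample(v) else v
  withSeed(seed, {
    idxIntra <- which(intra); idxInter <- which(!intra)
    if (nLinks <= length(idxIntra)) {
      chosen <- shuffle(idxIntra)[seq_len(nLinks)]
    } else {
      chosen <- c(idxIntra, shuffle(idxInter)[seq_len(nLinks - length(idxIntra))])
    }
    # group chosen links by unordered area pair, intra-module groups first
    # (random order within class); descending sorted weights are then dealt
    # out group by group, so intra-module links carry the largest weights
    # and reciprocal links get adjacent ranks (near-identical strengths)
    pairKey <- paste(pmin(src[chosen], tgt[chosen]),
                     pmax(src[chosen], tgt[chosen]))
    groups <- split(chosen, pairKey)
    groupIntra <- vapply(groups, function(g) intra[g[1]], logical(1))
    order <- c(shuffle(which(groupIntra)), shuffle(which(!groupIntra)))
    chosen <- unlist(groups[order], use.names = FALSE)
    wvals <- sort(rlnorm(nLinks, meanlog = 0, sdlog = 1) * weightScale,
                  decreasing = TRUE)
    w <- matrix(0, nAreas, nAreas)
    w[cbind(src[chosen], tgt[chosen])] <- wvals
    Connectome(w)
  })
}
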