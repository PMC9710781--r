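# internal helpers: condition classes, seed scoping, seed derivation

bioesnStop <- function(msg, class) {
  stop(structure(
    class = c(class, "bioesnError", "error", "condition"),
    list(message = msg, call = sys.call(-2))
  ))
}

formatError     <- function(msg) bioesnStop(msg, "bioesnFormatError")
validationError <- function(msg) bioesnStop(msg, "bioesnValidationError")
degenerateError <- function(msg) bioesnStop(msg, "bioesnDegenerateError")
ioError         <- function(msg) bioesnStop(msg, "bioesnIOError")

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# seed = NULL means "use the current stream as-is".
withSeed <- function(seed, expr) {
  if (is.null(seed) || (length(seed) == 1L && is.na(seed))) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L)
    validationError("`seed` must be a single integer or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic seed mixing for experiment cells: keeps every derived seed in
# [1, 2^31 - 2] so it is a valid R seed. Strings are folded to integers first.
deriveSeed <- function(base, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  fold <- function(v) {
    if (is.character(v)) v <- sum(utf8ToInt(v) * seq_along(utf8ToInt(v)))
    as.numeric(v) %% m
  }
  h <- as.numeric(base) %% m
  for (v in list(...)) {
    for (vi in v) h <- (h * 69069 + fold(vi) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# strict scalar checks used across constructors
checkScalar <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    validationError(sprintf("`%s` must be a single finite number", name))
  if (x < lower || x > upper)
    validationError(sprintf("`%s` must be in [%s, %s]", name, lower, upper))
  if (integer && x != round(x))
    validationError(sprintf("`%s` must be an integer", name))
  invisible(TRUE)
}
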