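#' Build an experiment plan
#'
#' A validated description of a replicate sweep over connectivity
#' conditions (and optionally upscaling sizes) on one task. Every
#' (condition, size, replicate) cell derives its own seed from `baseSeed`,
#' so replicates use newly instantiated weights while the whole sweep is
#' exactly repeatable.
#'
#' @param connectome the source [Connectome-class]
#' @param conditions subset of [reservoirConditions()]
#' @param task `"memory-capacity"` or `"sequence-recall"`
#' @param config an [ESNConfig-class]; for sequence recall the output
#'   activation is forced to ReLU
#' @param nReplicates replicate networks per cell (default 100, the
#'   full-protocol count; scale down for quick runs)
#' @param sizes neurons-per-area scaling factors (default 1: no upscaling)
#' @param interarealMode upscaling mode used when any size > 1
#' @param lags Memory Capacity lag set
#' @param patternLengths Sequence Recall difficulties L
#' @param tTrain,tTest Memory Capacity split (defaults 4000/1000 steps)
#' @param nTrainTrials,nTestTrials Sequence Recall split (defaults 800/200
#'   trials)
#' @param fixationLen fixation steps per trial (NA = patternLength)
#' @param k fan-in for `random-k` (default 10)
#' @param baseSeed base seed of the sweep
#' @return an [ExperimentPlan-class]
#' @seealso [runReplicates()]
#' @export
experimentPlan <- function(connectome, conditions, task = "memory-capacity",
                           config = esnConfig(), nReplicates = 100,
                           sizes = 1,
                           interarealMode = c("homogeneous",
                                              "heterogeneous"),
                           lags = 1:40, patternLengths = 5L,
                           tTrain = 4000, tTest = 1000,
                           nTrainTrials = 800, nTestTrials = 200,
                           fixationLen = NA, k = 10, baseSeed = 1) {
  interarealMode <- match.arg(interarealMode)
  if (task == "sequence-recall" && config@outputActivation != "relu")
    config@outputActivation <- "relu"
  new("ExperimentPlan",
      connectome = connectome, conditions = conditions, task = task,
      config = config, nReplicates = as.integer(nReplicates),
      sizes = as.integer(sizes), interarealMode = interarealMode,
      lags = as.integer(lags), patternLengths = as.integer(patternLengths),
      tTrain = as.integer(tTrain), tTest = as.integer(tTest),
      nTrainTrials = as.integer(nTrainTrials),
      nTestTrials = as.integer(nTestTrials),
      fixationLen = as.integer(fixationLen), k = as.integer(k),
      baseSeed = as.integer(baseSeed))
}

setMethod("show", "ExperimentPlan", function(object) {
  cat(sprintf(
    "ExperimentPlan: %s on %d-area connectome\n  conditions: %s\n",
    object@task, nAreas(object@connectome),
    paste(object@conditions, collapse = ", ")))
  cat(sprintf("  %d replicates, sizes {%s} (%s), base seed %d\n",
              object@nReplicates, paste(object@sizes, collapse = ", "),
              object@interarealMode, object@baseSeed))
})

# build, condition, scale and evaluate one experiment cell
runCell <- function(plan, condition, size, replicate) {
  cellSeed <- deriveSeed(plan@baseSeed, condition, size, replicate)
  src <- if (size > 1L)
    upscaleConnectome(plan@connectome, size, plan@interarealMode,
                      seed = deriveSeed(cellSeed, "upscale"))
  else plan@connectome
  res <- makeReservoir(src, condition,
                       seed = deriveSeed(cellSeed, "condition"),
                       k = plan@k)
  res <- scaleSpectralRadius(res, plan@config@spectralRadius)
  taskSeed <- deriveSeed(cellSeed, "task")
  if (plan@task == "memory-capacity") {
    ev <- runMemoryCapacity(res, plan@config, lags = plan@lags,
                            tTrain = plan@tTrain, tTest = plan@tTest,
                            seed = taskSeed)
    data.frame(condition = condition, task = plan@task,
               difficulty = c(plan@lags, NA),
               size = size, replicate = replicate, seed = cellSeed,
               metric = c(rep("rho2", length(plan@lags)), "mc"),
               score = c(unname(perOutputScores(ev)), aggregateScore(ev)))
  } else {
    fl <- plan@fixationLen
    rows <- lapply(plan@patternLengths, function(L) {
      ev <- runSequenceRecall(res, L, plan@config,
                              nTrainTrials = plan@nTrainTrials,
                              nTestTrials = plan@nTestTrials,
                              fixationLen = if (is.na(fl)) L else fl,
                              seed = deriveSeed(taskSeed, L))
      data.frame(condition = condition, task = plan@task, difficulty = L,
                 size = size, replicate = replicate, seed = cellSeed,
                 metric = "r2", score = aggregateScore(ev))
    })
    do.call(rbind, rows)
  }
}

#' Run a replicate sweep
#'
#' For each (condition, size, replicate) cell: build the connectivity
#' (upscaling first when size > 1), apply the surrogate condition, rescale
#' to the target spectral radius, train the readout and score the held-out
#' test split. Failures are isolated per cell (recorded in the `failures`
#' attribute of the result) so a long sweep is not aborted by one bad
#' cell.
#'
#' @param plan an [ExperimentPlan-class]
#' @return long-format `data.frame` with columns `connectome`, `condition`,
#'   `task`, `difficulty` (lag or pattern length; NA on Memory Capacity
#'   aggregate rows), `size`, `replicate`, `seed`, `metric`
#'   (`rho2`/`mc`/`r2`) and `score`; attribute `failures` holds any
#'   per-cell errors
#' @export
runReplicates <- function(plan) {
  stopifnot(is(plan, "ExperimentPlan"))
  cells <- expand.grid(condition = plan@conditions,
                       size = plan@sizes,
                       replicate = seq_len(plan@nReplicates),
                       stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells))
  failures <- list()
  for (i in seq_len(nrow(cells))) {
    out[[i]] <- tryCatch(
      runCell(plan, cells$condition[i], cells$size[i], cells$replicate[i]),
      error = function(e) {
        failures[[length(failures) + 1L]] <<- data.frame(
          condition = cells$condition[i], size = cells$size[i],
          replicate = cells$replicate[i], message = conditionMessage(e))
        NULL
      })
  }
  tab <- do.call(rbind, out)
  if (is.null(tab)) tab <- data.frame()
  else tab <- cbind(connectome = sprintf("connectome_%d_areas",
                                         nAreas(plan@connectome)), tab)
  fails <- if (length(failures)) do.call(rbind, failures) else NULL
  if (!is.null(fails))
    warning(sprintf("%d experiment cell(s) failed; see attr(, 'failures')",
                    nrow(fails)), call. = FALSE)
  attr(tab, "failures") <- fails
  tab
}

#' Aggregate Memory Capacity per replicate
#'
#' Convenience extraction of the MC rows of a [runReplicates()] table.
#'
#' @param tab result of [runReplicates()] on the memory-capacity task
#' @return data.frame with one MC row per condition x size x replicate
#' @export
memoryCapacityTable <- function(tab) tab[tab$metric == "mc", , drop = FALSE]

#' The full hyperparameter tuning grid
#'
#' All 300 constellations explored during tuning: spectral radius
#' `{0.91, 0.93, 0.95, 0.97, 0.99}`, input scaling `10^{-9} .. 10^0`,
#' leakage `{0.6, 0.8, 1}` and bias `{0, 1}`.
#'
#' @return data.frame with columns `spectralRadius`, `inputScaling`,
#'   `leakage`, `bias`, one row per constellation
#' @export
paperGrid <- function() {
  expand.grid(spectralRadius = c(0.91, 0.93, 0.95, 0.97, 0.99),
              inputScaling = 10^(-9:0),
              leakage = c(0.6, 0.8, 1),
              bias = c(0, 1))
}

#' Grid search over ESN hyperparameters
#'
#' Trains every constellation with `nReservoirs` independently generated
#' reservoirs and selects the constellation with the best mean validation
#' score (ties: first row of the grid). Validation carves the last 20% of
#' the training span: for Memory Capacity the last 20% of the training
#' steps, for Sequence Recall the last 20% of the training trials. Pass a
#' single-row grid to "fix" a constellation without searching.
#'
#' @param connectome source [Connectome-class]
#' @param condition one of [reservoirConditions()]
#' @param task `"memory-capacity"` or `"sequence-recall"`
#' @param grid data.frame of constellations (see [paperGrid()]); must be
#'   non-empty
#' @param nReservoirs independent reservoirs per constellation (default
#'   10)
#' @param lags,patternLength task difficulty settings
#' @param tTrain Memory Capacity training span to carve (default 4000)
#' @param nTrainTrials Sequence Recall training trials to carve (default
#'   800)
#' @param k fan-in for `random-k`
#' @param baseSeed base seed
#' @return list with `table` (constellation x reservoir validation scores)
#'   and `best` (the selected [ESNConfig-class])
#' @export
gridSearch <- function(connectome, condition, task = "memory-capacity",
                       grid = paperGrid(), nReservoirs = 10,
                       lags = 1:40, patternLength = 5,
                       tTrain = 4000, nTrainTrials = 800, k = 10,
                       baseSeed = 1) {
  if (!is.data.frame(grid) || nrow(grid) == 0)
    validationError("`grid` must be a non-empty data.frame")
  need <- c("spectralRadius", "inputScaling", "leakage", "bias")
  if (!all(need %in% names(grid)))
    validationError(sprintf("`grid` must have columns %s",
                            paste(need, collapse = ", ")))
  rows <- vector("list", nrow(grid) * nReservoirs)
  ri <- 0L
  for (g in seq_len(nrow(grid))) {
    for (r in seq_len(nReservoirs)) {
      seed <- deriveSeed(baseSeed, "grid", g, r)
      cfg <- esnConfig(
        spectralRadius = grid$spectralRadius[g],
        inputScaling = grid$inputScaling[g],
        leakage = grid$leakage[g], bias = grid$bias[g],
        outputActivation = if (task == "sequence-recall") "relu"
                           else "identity")
      res <- makeReservoir(connectome, condition,
                           seed = deriveSeed(seed, "condition"), k = k)
      res <- scaleSpectralRadius(res, cfg@spectralRadius)
      score <- if (task == "memory-capacity") {
        nVal <- round(0.2 * tTrain)
        aggregateScore(runMemoryCapacity(
          res, cfg, lags = lags, tTrain = tTrain - nVal, tTest = nVal,
          seed = deriveSeed(seed, "task")))
      } else {
        nVal <- round(0.2 * nTrainTrials)
        aggregateScore(runSequenceRecall(
          res, patternLength, cfg, nTrainTrials = nTrainTrials - nVal,
          nTestTrials = nVal, seed = deriveSeed(seed, "task")))
      }
      ri <- ri + 1L
      rows[[ri]] <- cbind(grid[g, , drop = FALSE],
                          constellation = g, reservoir = r,
                          validationScore = score, row.names = NULL)
    }
  }
  tab <- do.call(rbind, rows)
  means <- tapply(tab$validationScore, tab$constellation, mean)
  bestIdx <- as.integer(names(means)[which.max(means)]) # stable: first max
  best <- esnConfig(
    spectralRadius = grid$spectralRadius[bestIdx],
    inputScaling = grid$inputScaling[bestIdx],
    leakage = grid$leakage[bestIdx], bias = grid$bias[bestIdx],
    outputActivation = if (task == "sequence-recall") "relu" else "identity")
  list(table = tab, best = best, bestConstellation = bestIdx)
}

#' Write a results table with a reproducibility manifest
#'
#' Writes the long-format results as CSV and a JSON manifest (arguments,
#' seeds, package version, timestamp) next to it as `<path>.manifest.json`.
#'
#' @param tab data.frame from [runReplicates()] or [gridSearch()]
#' @param path output CSV path
#' @param manifest optional named list folded into the manifest
#' @return invisibly, `path`
#' @export
writeResultsTable <- function(tab, path, manifest = list()) {
  utils::write.csv(tab, path, row.names = FALSE)
  m <- c(list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "bioesn",
    version = as.character(utils::packageVersion("bioesn")),
    rows = nrow(tab)), manifest)
  jsonlite::write_json(m, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
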