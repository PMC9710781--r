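smallPlan <- function(con, conditions, nReplicates = 3, ...) {
  experimentPlan(con, conditions, "memory-capacity",
                 nReplicates = nReplicates, lags = 1:5,
                 tTrain = 400, tTest = 200, baseSeed = 42, ...)
}

test_that("replicate sweeps produce one record per cell and difficulty", {
  con <- randomConnectome(12, 0.4, seed = 1)
  tab <- runReplicates(smallPlan(con, c("bio-rank", "bio-no-rank")))
  mc <- memoryCapacityTable(tab)
  expect_equal(nrow(mc), 2 * 3)
  expect_equal(nrow(tab[tab$metric == "rho2", ]), 2 * 3 * 5)
  expect_true(all(is.finite(tab$score)))
  expect_setequal(unique(tab$condition), c("bio-rank", "bio-no-rank"))
})

test_that("sweeps are exactly repeatable and cells get distinct seeds", {
  con <- randomConnectome(12, 0.4, seed = 2)
  p <- smallPlan(con, c("bio-rank", "random-full"))
  t1 <- runReplicates(p)
  t2 <- runReplicates(p)
  attr(t1, "failures") <- attr(t2, "failures") <- NULL
  expect_identical(t1, t2)
  expect_equal(anyDuplicated(unique(t1[, c("condition", "replicate",
                                           "seed")])$seed), 0)
})

test_that("failing cells are isolated, recorded and do not abort the sweep", {
  con <- randomConnectome(12, 0.4, seed = 3)
  # k = 50 is impossible on a 12-neuron reservoir -> every random-k cell
  # fails while bio-no-rank cells succeed
  p <- smallPlan(con, c("bio-no-rank", "random-k"), k = 50)
  expect_warning(tab <- runReplicates(p), "failed")
  expect_equal(unique(tab$condition), "bio-no-rank")
  fails <- attr(tab, "failures")
  expect_equal(nrow(fails), 3)
  expect_match(fails$message[1], "degree|exceeds")
})

test_that("sequence recall sweeps cover each pattern length", {
  con <- randomConnectome(12, 0.4, seed = 4)
  p <- experimentPlan(con, "bio-no-rank", "sequence-recall",
                      nReplicates = 2, patternLengths = c(2L, 3L),
                      nTrainTrials = 80, nTestTrials = 40, baseSeed = 7)
  tab <- runReplicates(p)
  expect_equal(nrow(tab), 2 * 2)
  expect_setequal(tab$difficulty, c(2, 3))
  expect_true(all(tab$metric == "r2"))
})

test_that("the tuning grid enumerates all printed constellations", {
  g <- paperGrid()
  expect_equal(nrow(g), 300) # 5 radii x 10 scalings x 3 leakages x 2 biases
  expect_equal(length(unique(g$spectralRadius)), 5)
  expect_equal(length(unique(g$inputScaling)), 10)
  expect_equal(length(unique(g$leakage)), 3)
  expect_equal(length(unique(g$bias)), 2)
})

test_that("grid search selects the best mean validation score", {
  con <- randomConnectome(15, 0.4, seed = 5)
  # a sane constellation against one with absurdly large input scaling
  grid <- data.frame(spectralRadius = c(0.99, 0.99),
                     inputScaling = c(1e-5, 1e3),
                     leakage = 1, bias = c(1, 0))
  gs <- gridSearch(con, "bio-no-rank", grid = grid, nReservoirs = 3,
                   lags = 1:5, tTrain = 500, baseSeed = 9)
  expect_equal(nrow(gs$table), 6)
  means <- tapply(gs$table$validationScore, gs$table$constellation, mean)
  expect_equal(gs$bestConstellation, as.integer(names(which.max(means))))
  expect_equal(gs$best@inputScaling,
               grid$inputScaling[gs$bestConstellation])

  # single-row grid: selection returns it untouched
  one <- gridSearch(con, "bio-no-rank", grid = grid[1, ], nReservoirs = 2,
                    lags = 1:5, tTrain = 500, baseSeed = 9)
  expect_equal(one$bestConstellation, 1L)
  expect_equal(one$best@spectralRadius, 0.99)

  expect_error(gridSearch(con, "bio-no-rank", grid = data.frame()),
               class = "bioesnValidationError")
})

test_that("the fixed constellation learns the task under every condition", {
  con <- synthConnectome(30, 3, 0.35, seed = 1)
  for (cn in reservoirConditions()) {
    W <- scaleSpectralRadius(makeReservoir(con, cn, seed = 13))
    ev <- runMemoryCapacity(W, lags = 1:10, tTrain = 1000, tTest = 500,
                            seed = 14)
    expect_gt(aggregateScore(ev), 0)
  }
})

test_that("results tables serialize with a manifest", {
  con <- randomConnectome(12, 0.4, seed = 6)
  tab <- runReplicates(smallPlan(con, "bio-rank", nReplicates = 1))
  f <- tempfile(fileext = ".csv")
  writeResultsTable(tab, f, manifest = list(baseSeed = 42))
  expect_true(file.exists(f))
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(tab))
  m <- jsonlite::read_json(paste0(f, ".manifest.json"))
  expect_equal(m$baseSeed, 42)
  expect_equal(m$package, "bioesn")
})
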