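test_that("memory capacity targets are exact lagged copies of the input", {
  d <- makeMemoryCapacityData(10, lags = 1L, seed = 1)
  expect_true(is.na(d@y[1, 1]))
  expect_equal(d@y[2:10, 1], d@x[1:9, 1])
  expect_true(all(d@x > -0.5 & d@x < 0.5))
  expect_identical(d@x, makeMemoryCapacityData(10, lags = 1L, seed = 1)@x)
  expect_error(makeMemoryCapacityData(10, lags = c(5L, 10L)),
               class = "bioesnDegenerateError")
  expect_error(makeMemoryCapacityData(10, lags = c(3L, 2L)),
               class = "bioesnValidationError")
})

test_that("memory capacity scoring sums squared Pearson correlations", {
  d <- makeMemoryCapacityData(500, lags = 1:20, seed = 2)
  y <- d@y[30:500, ]
  ev <- scoreMemoryCapacity(y, y, 1:20)
  expect_equal(unname(perOutputScores(ev)), rep(1, 20))
  expect_equal(aggregateScore(ev), 20)

  # Pearson is affine-invariant
  ev2 <- scoreMemoryCapacity(y, 2 * y + 3, 1:20)
  expect_equal(aggregateScore(ev2), 20)

  # constant predictions carry no memory content
  ev3 <- scoreMemoryCapacity(y, y * 0 + 1, 1:20)
  expect_equal(aggregateScore(ev3), 0)
})

test_that("independent predictions score near the analytic chance level", {
  # null rho^2 has mean 1/(n-1); Monte-Carlo over replicates
  set.seed(3)
  n <- 1000
  scores <- replicate(300, cor(runif(n), runif(n))^2)
  expect_equal(mean(scores), 1 / (n - 1), tolerance = 0.15)
  d <- makeMemoryCapacityData(n + 50, lags = 1:10, seed = 4)
  y <- d@y[51:(n + 50), ]
  ev <- scoreMemoryCapacity(y, matrix(runif(n * 10), n, 10), 1:10)
  expect_lt(aggregateScore(ev), 10 * 5 / (n - 1)) # well below 5x chance
  expect_true(all(perOutputScores(ev) >= 0 & perOutputScores(ev) <= 1))
})

test_that("sequence recall trials have the documented structure", {
  d <- makeSequenceRecallData(1, patternLength = 2, fixationLen = 2,
                              seed = 5)
  # recall targets are the two fixation inputs in order
  expect_equal(d@y[3:4, 1], d@x[1:2, "x1"])
  expect_equal(d@y[1:2, 1], c(0, 0))
  expect_equal(d@x[3:4, "x2"], c(1, 1))
  expect_equal(d@x[3:4, "x1"], c(0, 0))

  d2 <- makeSequenceRecallData(200, 5, seed = 6)
  expect_equal(nrow(d2@x), 200 * 10)
  expect_true(all(d2@y[d2@x[, "x2"] == 0, 1] == 0))
  expect_true(all(d2@x[, "x1"] >= 0 & d2@x[, "x1"] < 1))
  expect_equal(nrow(d2@trials), 200)

  # pattern longer than the fixation period cannot be recalled in full
  expect_error(makeSequenceRecallData(10, 5, fixationLen = 3),
               class = "bioesnDegenerateError")
})

test_that("recall scoring uses only recall steps", {
  d <- makeSequenceRecallData(50, 3, seed = 7)
  y <- d@y[, 1]
  recall <- recallSteps(d)
  expect_equal(aggregateScore(scoreSequenceRecall(y, y, recall)), 1)

  # predicting the mean of the recall targets scores exactly 0
  yhat <- y; yhat[recall] <- mean(y[recall])
  expect_equal(aggregateScore(scoreSequenceRecall(y, yhat, recall)), 0)

  # perturbing fixation predictions cannot change the score
  set.seed(8)
  noisy <- y + rnorm(length(y), sd = 0.3)
  a <- scoreSequenceRecall(y, noisy, recall)
  messedFix <- noisy; messedFix[!recall] <- 99
  b <- scoreSequenceRecall(y, messedFix, recall)
  expect_identical(aggregateScore(a), aggregateScore(b))

  expect_error(scoreSequenceRecall(y, y, rep(FALSE, length(y))),
               class = "bioesnDegenerateError")
})

test_that("task wrappers train, reinitialize at test time and score", {
  W <- scaleSpectralRadius(makeRandomFull(30, seed = 9))
  ev <- runMemoryCapacity(W, lags = 1:10, tTrain = 800, tTest = 400,
                          seed = 10)
  expect_true(all(perOutputScores(ev) >= 0 & perOutputScores(ev) <= 1))
  expect_lte(aggregateScore(ev), 10)
  expect_gt(aggregateScore(ev), 1) # a working reservoir remembers something
  expect_equal(aggregateScore(ev),
               aggregateScore(runMemoryCapacity(W, lags = 1:10,
                                                tTrain = 800, tTest = 400,
                                                seed = 10)))

  ev2 <- runSequenceRecall(W, patternLength = 3, nTrainTrials = 150,
                           nTestTrials = 60, seed = 11)
  expect_lte(aggregateScore(ev2), 1)
  expect_gt(aggregateScore(ev2), 0.5)
})
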