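test_that("input weights are dense uniform [-1, 1] and reproducible", {
  win <- initInputWeights(200, 1, seed = 1)
  expect_equal(dim(win), c(200, 1))
  expect_true(all(win >= -1 & win <= 1))
  expect_identical(win, initInputWeights(200, 1, seed = 1))
})

test_that("the C++ recursion matches a plain R oracle step for step", {
  set.seed(2)
  n <- 4; T <- 20
  W <- matrix(runif(n * n, -0.4, 0.4), n, n); diag(W) <- 0
  Win <- matrix(runif(n, -1, 1), n, 1)
  x <- matrix(runif(T, -0.5, 0.5), ncol = 1)
  for (form in c("standard", "printed")) {
    cfg <- esnConfig(inputScaling = 0.3, leakage = 0.7, bias = 0.5,
                     leakIntegration = form)
    r <- numeric(n); ref <- matrix(0, T, n)
    for (t in 1:T) {
      wr <- W %*% r
      rp <- tanh(Win %*% (0.3 * x[t, ]) + wr + 0.5)
      r <- 0.7 * rp + 0.3 * (if (form == "printed") wr else r)
      ref[t, ] <- r
    }
    got <- runReservoir(x, W, Win, cfg)@states
    expect_equal(got, ref, tolerance = 1e-14, info = form)
  }
})

test_that("zero drive gives the zero fixed point; alpha = 1 collapses the
           two leak forms", {
  W <- scaleSpectralRadius(matrix(runif(25), 5, 5) - 0.5, 0.9)
  x <- matrix(runif(50), ncol = 1)
  cfg0 <- esnConfig(bias = 0)
  s <- runReservoir(x, W, matrix(0, 5, 1), cfg0)@states
  expect_true(all(s == 0))

  Win <- initInputWeights(5, 1, seed = 3)
  a <- runReservoir(x, W, Win, esnConfig(leakage = 1))@states
  b <- runReservoir(x, W, Win,
                    esnConfig(leakage = 1, leakIntegration = "printed"))@states
  expect_identical(a, b)

  # with leakage < 1 the printed variant genuinely differs
  a2 <- runReservoir(x, W, Win, esnConfig(leakage = 0.6))@states
  b2 <- runReservoir(x, W, Win,
                     esnConfig(leakage = 0.6,
                               leakIntegration = "printed"))@states
  expect_gt(max(abs(a2 - b2)), 0)
})

test_that("tanh states are bounded in [-1, 1] even under strong drive", {
  W <- scaleSpectralRadius(weightMatrix(makeRandomFull(30, seed = 4)), 0.99)
  Win <- initInputWeights(30, 1, seed = 5)
  x <- matrix(runif(300, -50, 50), ncol = 1)
  s <- runReservoir(x, W, Win, esnConfig(inputScaling = 1))@states
  expect_true(all(s >= -1 & s <= 1))
})

test_that("a linear shift reservoir is an exact delay line", {
  n <- 12; T <- 60
  x <- matrix(runif(T, -0.5, 0.5), ncol = 1)
  Win <- matrix(c(1, rep(0, n - 1)), n, 1)
  cfg <- esnConfig(inputScaling = 1, bias = 0,
                   reservoirActivation = "identity")
  s <- runReservoir(x, shiftMatrix(n), Win, cfg)@states
  for (i in 1:n)
    expect_equal(s[i:T, i], x[1:(T - i + 1), 1], tolerance = 1e-14)
})

test_that("echo state property: different initial states converge", {
  W <- scaleSpectralRadius(weightMatrix(makeRandomFull(40, seed = 6)), 0.9)
  Win <- initInputWeights(40, 1, seed = 7)
  x <- matrix(runif(500, -0.5, 0.5), ncol = 1)
  cfg <- esnConfig(inputScaling = 1, bias = 0)
  s0 <- runReservoir(x, W, Win, cfg)@states
  s1 <- runReservoir(x, W, Win, cfg, r0 = runif(40, -1, 1))@states
  expect_lt(max(abs(s0[500, ] - s1[500, ])), 1e-6)
})

test_that("pseudoinverse readout matches the normal-equations oracle", {
  set.seed(8)
  T <- 50; n <- 5
  W <- scaleSpectralRadius(matrix(runif(n^2), n, n) - 0.5, 0.9)
  Win <- initInputWeights(n, 1, seed = 9)
  x <- matrix(runif(T, -0.5, 0.5), ncol = 1)
  y <- matrix(runif(T * 2), ncol = 2)
  cfg <- esnConfig(inputScaling = 1, transient = 10)
  states <- runReservoir(x, W, Win, cfg)@states
  ro <- fitReadout(x, states, y, cfg)

  Z <- cbind(x, states)[-(1:10), ]
  Y <- y[-(1:10), ]
  oracle <- solve(crossprod(Z)) %*% crossprod(Z, Y) # full column rank
  expect_equal(ro@weights, t(oracle), tolerance = 1e-8)

  # an input column is in the regressor set, so it is fit exactly
  ro2 <- fitReadout(x, states, x, cfg)
  pred <- predictOutput(x, states, ro2)
  expect_equal(pred[-(1:10), 1], x[-(1:10), 1], tolerance = 1e-8)

  expect_error(fitReadout(x[1:10, , drop = FALSE], states[1:10, ],
                          y[1:10, ], cfg),
               class = "bioesnDegenerateError")
})

test_that("output activation is applied at prediction time", {
  set.seed(10)
  states <- matrix(runif(60, -1, 1), 20, 3)
  x <- matrix(runif(20), ncol = 1)
  ro <- new("Readout", weights = matrix(rnorm(4), 1, 4),
            outputActivation = "relu", nInputs = 1L)
  expect_true(all(predictOutput(x, states, ro) >= 0))
  ro0 <- new("Readout", weights = matrix(0, 1, 4),
             outputActivation = "identity", nInputs = 1L)
  expect_true(all(predictOutput(x, states, ro0) == 0))
  expect_error(predictOutput(cbind(x, x), states, ro),
               class = "bioesnValidationError")
})
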