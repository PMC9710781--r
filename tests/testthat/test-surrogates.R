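test_that("link weight sampling is uniform on [-1, 1], nonzero, reproducible", {
  expect_length(sampleLinkWeights(0), 0)
  w <- sampleLinkWeights(1e5, seed = 42)
  expect_true(all(w >= -1 & w <= 1 & w != 0))
  # CLT bound: sd of Uniform[-1,1] is 2/sqrt(12)
  expect_lt(abs(mean(w)), 3 * (2 / sqrt(12)) / sqrt(1e5))
  expect_identical(w, sampleLinkWeights(1e5, seed = 42))
})

test_that("bio-rank preserves topology and the full rank order", {
  con <- toyTriangle() # strengths a->b 5, b->c 1, c->a 3
  r <- makeBioRank(con, seed = 7)
  expect_identical(linkMask(r), linkMask(con))
  w <- weightMatrix(r)
  # weakest empirical link (b->c) carries the smallest sampled weight,
  # strongest (a->b) the largest
  expect_true(w[2, 3] < w[3, 1] && w[3, 1] < w[1, 2])

  big <- randomConnectome(25, 0.4, seed = 2)
  rb <- makeBioRank(big, seed = 3)
  expect_equal(linkSpearman(weightMatrix(big), weightMatrix(rb)), 1)

  # single link: it carries the single sampled weight
  w1 <- matrix(0, 2, 2); w1[1, 2] <- 4
  r1 <- makeBioRank(Connectome(w1), seed = 1)
  expect_equal(sum(weightMatrix(r1) != 0), 1)

  expect_error(makeBioRank(Connectome(matrix(0, 3, 3))),
               class = "bioesnDegenerateError")
})

test_that("bio-rank breaks empirical ties by (source, target) index order", {
  w <- matrix(1, 4, 4); diag(w) <- 0 # all strengths tied
  con <- Connectome(w)
  r <- makeBioRank(con, seed = 9)
  ind <- which(linkMask(con) == 1, arr.ind = TRUE)
  ind <- ind[order(ind[, 1], ind[, 2]), ]
  assigned <- weightMatrix(r)[ind]
  expect_identical(assigned, sort(assigned))
})

test_that("bio-no-rank keeps the mask but scrambles the ranks", {
  con <- randomConnectome(20, 0.5, seed = 4)
  r <- makeBioNoRank(con, seed = 5)
  expect_identical(linkMask(r), linkMask(con))

  # null distribution of Spearman's rho: sd ~ 1/sqrt(n - 1); the
  # seed-averaged correlation over 100 seeds on a 10^4-link graph is tiny
  big <- synthConnectome(101, 1, 0.99, seed = 6) # 9900+ links
  rhos <- vapply(1:100, function(s)
    linkSpearman(weightMatrix(big),
                 weightMatrix(makeBioNoRank(big, seed = s))), numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("random-density conserves the link count with uniform placement", {
  con <- randomConnectome(20, 0.31, seed = 8)
  r <- makeRandomDensity(con, seed = 9)
  expect_equal(nLinks(r), nLinks(con))

  full <- synthConnectome(8, 1, 1, seed = 1)
  expect_equal(nLinks(makeRandomDensity(full, seed = 2)), 56)

  # per-pair inclusion frequency over 200 seeds is binomial around density
  dens <- linkDensity(con)
  count <- matrix(0, 20, 20)
  for (s in 1:200) count <- count + linkMask(makeRandomDensity(con, seed = s))
  off <- row(count) != col(count)
  freq <- count[off] / 200
  sd3 <- 3 * sqrt(dens * (1 - dens) / 200)
  expect_gt(mean(abs(freq - dens) <= sd3), 0.97)
  expect_true(all(abs(freq - dens) <= 4.5 * sd3 / 3))
})

test_that("random-k fixes the fan-in exactly", {
  r <- makeRandomK(50, 10, seed = 1)
  expect_equal(unname(colSums(linkMask(r))), rep(10, 50))
  expect_equal(nLinks(r), 500)

  expect_equal(nLinks(makeRandomK(5, 4, seed = 2)), 20) # fully connected
  expect_error(makeRandomK(5, 5, seed = 3), class = "bioesnDegenerateError")

  rout <- makeRandomK(30, 7, seed = 4, degree = "out")
  expect_equal(unname(rowSums(linkMask(rout))), rep(7, 30))
})

test_that("random-full is fully connected with seed-dependent weights", {
  r1 <- makeRandomFull(10, seed = 1)
  r2 <- makeRandomFull(10, seed = 2)
  expect_equal(nLinks(r1), 90)
  expect_equal(linkDensity(r1), 1)
  expect_true(all(diag(linkMask(r1)) == 0))
  expect_identical(linkMask(r1), linkMask(r2))
  expect_false(identical(weightMatrix(r1), weightMatrix(r2)))
})

test_that("all conditions give signed pre-scaling weights in [-1, 1], zero
           diagonal, and are seed-deterministic", {
  con <- randomConnectome(15, 0.4, seed = 3)
  for (cn in reservoirConditions()) {
    r <- makeReservoir(con, cn, seed = 21)
    w <- weightMatrix(r)
    expect_true(all(w >= -1 & w <= 1), info = cn)
    expect_true(all(diag(w) == 0), info = cn)
    expect_true(all((w != 0) == (linkMask(r) == 1)), info = cn)
    expect_identical(w, weightMatrix(makeReservoir(con, cn, seed = 21)),
                     info = cn)
    expect_identical(conditionName(r), cn)
  }
  expect_error(makeReservoir(con, "bio_ranked"),
               class = "bioesnValidationError")
})

test_that("spectral scaling imposes the exact target radius", {
  # 2-cycle has eigenvalues +-1, so scaling is a pure multiplication
  twoCycle <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(scaleSpectralRadius(twoCycle, 0.99),
               matrix(c(0, 0.99, 0.99, 0), 2, 2))

  r <- makeRandomDensity(randomConnectome(20, 0.3, seed = 5), seed = 6)
  rs <- scaleSpectralRadius(r, 0.99)
  expect_equal(spectralRadius(rs), 0.99, tolerance = 1e-8)
  expect_identical(linkMask(rs), linkMask(r))

  # strictly triangular wiring is nilpotent: true spectral radius 0
  tri <- matrix(0, 10, 10); tri[upper.tri(tri)] <- runif(45)
  expect_error(scaleSpectralRadius(tri), class = "bioesnDegenerateError")
})
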