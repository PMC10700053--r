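test_that("Gaussian kernel matches its closed form", {
  expect_equal(gaussianKernel(0), 1 / sqrt(2 * pi))
  u <- c(-3, -0.5, 0.1, 2)
  expect_equal(gaussianKernel(u), gaussianKernel(-u))
  expect_equal(gaussianKernel(1) / gaussianKernel(0), exp(-1 / 2))
})

test_that("NW estimates are normalized weighted averages", {
  # a single sample dominates everywhere
  one <- nwEstimate(matrix(c(5, 5), 1), matrix(c(1, 1), 1), y = 3.7,
                    h = c(2, 2), massFloor = 0)
  expect_equal(one$estimate, 3.7)
  # two samples equidistant from the query average exactly
  two <- nwEstimate(matrix(c(0, 0), 1), rbind(c(-1, 0), c(1, 0)),
                    y = c(2, 6), h = c(1, 1))
  expect_equal(two$estimate, 4)
})

test_that("NW agrees with the double-loop oracle and is order-invariant", {
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    d <- sample(2:3, 1)
    X <- matrix(runif(n * d, 0, 10), ncol = d)
    y <- rnorm(n)
    q <- matrix(runif(4 * d, 0, 10), ncol = d)
    h <- runif(d, 0.5, 3)
    est <- nwEstimate(q, X, y, h, massFloor = 0)$estimate
    expect_equal(est, nwOracle(q, X, y, h), tolerance = 1e-12)
    # convex-combination property
    expect_true(all(est >= min(y) - 1e-12 & est <= max(y) + 1e-12))
    # sample order is irrelevant
    p <- sample(n)
    expect_equal(nwEstimate(q, X[p, ], y[p], h, massFloor = 0)$estimate, est,
                 tolerance = 1e-12)
  }
})

test_that("the separable lattice path equals the generic path", {
  set.seed(11)
  rec <- data.frame(x2 = runif(300, 100, 700), x3 = runif(300, 3, 30),
                    g = rnorm(300), f = abs(rnorm(300, 0.03, 0.01)))
  grid <- enumerateGrid(ParameterBounds(100, 700, 3, 30), stepX2 = 25L)
  surf <- smoothSurface(rec, grid) # lattice fast path
  gen <- nwEstimate(as.matrix(grid[, c("x2", "x3")]),
                    as.matrix(rec[, c("x2", "x3")]), rec$g, c(30, 1))
  expect_equal(surf@gHat, gen$estimate, tolerance = 1e-12)
  expect_equal(surf@massG, gen$mass, tolerance = 1e-12)
})

test_that("weight-mass underflow flags far-away grid points missing", {
  rec <- data.frame(x2 = runif(200, 100, 200), x3 = runif(200, 14, 16),
                    g = rnorm(200), f = 0.02)
  far <- nwEstimate(matrix(c(700, 30), 1),
                    as.matrix(rec[, c("x2", "x3")]), rec$g, c(30, 1))
  expect_true(far$missing)
  expect_true(is.na(far$estimate))
  near <- nwEstimate(matrix(c(150, 15), 1),
                     as.matrix(rec[, c("x2", "x3")]), rec$g, c(30, 1))
  expect_false(near$missing)
})

test_that("surface smoothing preserves constants and flattens at huge h", {
  rec <- data.frame(x2 = seq(100, 700, by = 40), x3 = rep(3:18, length.out = 16),
                    g = 7, f = 0.02)
  grid <- enumerateGrid(stepX2 = 100L, stepX3 = 5L)
  s <- smoothSurface(rec, grid, massFloor = 0)
  expect_equal(s@gHat, rep(7, nrow(grid)))
  # f's narrower bandwidth loses all kernel mass at a few far corners of
  # this sparse fixture; the composite is constant wherever it is defined
  expect_equal(s@mHat[!s@missing], rep(7 - 50 * 0.02, sum(!s@missing)))

  set.seed(12)
  rec$g <- rnorm(16)
  huge <- smoothSurface(rec, grid, Bandwidths(c(x2 = 1e6, x3 = 1e6)),
                        massFloor = 0)
  expect_equal(huge@gHat, rep(mean(rec$g), nrow(grid)), tolerance = 1e-6)
})

test_that("noiseless linear responses are recovered on the interior", {
  set.seed(13)
  rec <- data.frame(x2 = runif(2000, 100, 700), x3 = runif(2000, 3, 30))
  rec$g <- 0.01 * rec$x2 + 0.2 * rec$x3
  rec$f <- 0.02
  grid <- enumerateGrid(ParameterBounds(200, 600, 8, 25), stepX2 = 50L,
                        stepX3 = 4L)
  s <- smoothSurface(rec, grid, massFloor = 0)
  truth <- 0.01 * grid$x2 + 0.2 * grid$x3
  # interior bias of a locally-centred kernel average of a linear function
  # is small relative to the response range (~8 units here)
  expect_lt(max(abs(s@gHat - truth)), 0.35)
})

test_that("linear baseline interpolates exactly and flags the hull", {
  rec <- data.frame(x2 = c(0, 10, 0, 10, 5), x3 = c(0, 0, 10, 10, 5),
                    g = c(0, 1, 2, 3, 1.5), f = 0)
  rec$m <- rec$g
  grid <- data.frame(x2 = c(0, 10, 20), x3 = c(0, 10, 2))
  s <- linearBaselineSurface(rec, grid)
  expect_equal(s@gHat[1:2], c(0, 3), tolerance = 1e-4)
  expect_true(s@missing[3])

  # centroid of a triangle with vertex values (0, 0, 3) -> 1
  tri <- data.frame(x2 = c(0, 3, 0), x3 = c(0, 0, 3), g = c(0, 0, 3), f = 0)
  cen <- linearBaselineSurface(tri, data.frame(x2 = 1, x3 = 1))
  expect_equal(cen@gHat, 1, tolerance = 1e-4)

  # duplicate locations are pre-averaged
  dup <- rbind(tri, data.frame(x2 = 0, x3 = 0, g = 2, f = 0))
  at0 <- linearBaselineSurface(dup, data.frame(x2 = 0, x3 = 0))
  expect_equal(at0@gHat, 1, tolerance = 1e-4)
})

test_that("linear baseline reproduces linear functions inside the hull", {
  set.seed(14)
  rec <- data.frame(x2 = runif(80, 0, 10), x3 = runif(80, 0, 10))
  rec$g <- 2 + 0.5 * rec$x2 - 0.25 * rec$x3
  rec$f <- 0
  q <- data.frame(x2 = runif(30, 2, 8), x3 = runif(30, 2, 8))
  s <- linearBaselineSurface(rec, q)
  expect_equal(s@gHat, 2 + 0.5 * q$x2 - 0.25 * q$x3, tolerance = 1e-5)
})

test_that("degenerate geometry is rejected", {
  line <- data.frame(x2 = 1:5, x3 = 1:5, g = 1, f = 0) # collinear
  expect_error(linearBaselineSurface(line, data.frame(x2 = 2, x3 = 2)),
               "triangulation|degenerate")
  two <- data.frame(x2 = c(1, 2), x3 = c(1, 2), g = 1, f = 0)
  expect_error(linearBaselineSurface(two, data.frame(x2 = 2, x3 = 2)),
               "degenerate")
})

test_that("kernel smoothing beats linear interpolation on noisy surfaces", {
  # density regime of the intended use: many noisy realizations relative to
  # the grid, so interpolation chases the noise while the kernel averages it
  # out; a gentle surface keeps the kernel's smoothing bias subordinate
  obj <- quadraticObjective(curvature = c(2e-4, 0.02))
  grid <- enumerateGrid(ParameterBounds(150, 650, 5, 28), stepX2 = 20L)
  truth <- 10 - 2e-4 * (grid$x2 - 400)^2 - 0.02 * (grid$x3 - 15)^2
  wins <- 0
  for (s in 1:20) {
    rec <- generateSyntheticRecords(obj, 2000, seed = s)
    nw <- smoothSurface(rec, grid)
    lin <- linearBaselineSurface(rec, grid)
    ok <- !nw@missing & !lin@missing
    mseNW <- mean((nw@mHat[ok] - truth[ok])^2)
    mseLin <- mean((lin@mHat[ok] - truth[ok])^2)
    wins <- wins + (mseNW < mseLin)
  }
  expect_gt(wins, 15)
})

test_that("cross-validation picks sane bandwidths", {
  cand <- list(tiny = Bandwidths(c(x2 = 2, x3 = 0.1)),
               moderate = Bandwidths(c(x2 = 30, x3 = 1)),
               huge = Bandwidths(c(x2 = 5000, x3 = 500)))
  # single candidate: returned as-is
  rec <- generateSyntheticRecords(quadraticObjective(), 200, seed = 1)
  expect_identical(hValues(cvBandwidth(rec, cand[2])), hValues(cand[[2]]))

  # smooth noiseless quadratic: huge over-smoothing is never selected
  noiseless <- quadraticObjective(noiseSdG = 0, noiseSdF = 0)
  recN <- generateSyntheticRecords(noiseless, 300, seed = 2)
  pick <- cvBandwidth(recN, cand, response = "g")
  expect_lt(hValues(pick)[["x2"]], 5000)

  # pure noise: the largest candidate wins in most repetitions
  flat <- syntheticObjective(function(x2, x3) rep(0, length(x2)),
                             function(x2, x3) rep(0, length(x2)),
                             noiseSdG = 1, noiseSdF = 0, argmax = c(400, 15))
  largest <- 0
  for (s in 1:7) {
    recF <- generateSyntheticRecords(flat, 120, seed = s)
    pickF <- cvBandwidth(recF, cand, response = "g")
    largest <- largest + (hValues(pickF)[["x2"]] == 5000)
  }
  expect_gt(largest, 3.5)

  # k-fold path is deterministic given the fold seed
  big <- generateSyntheticRecords(quadraticObjective(), 700, seed = 3)
  p1 <- cvBandwidth(big, cand, looThreshold = 100, foldSeed = 5)
  p2 <- cvBandwidth(big, cand, looThreshold = 100, foldSeed = 5)
  expect_identical(attr(p1, "cvError"), attr(p2, "cvError"))
})
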