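makeSurface <- function(grid, m) {
  new("KernelSurface", grid = grid, gHat = m, fHat = rep(0, nrow(grid)),
      mHat = m, massG = rep(1, nrow(grid)), massF = rep(1, nrow(grid)),
      missing = rep(FALSE, nrow(grid)), bandwidths = Bandwidths(),
      method = "nw")
}

test_that("brute-force argmax breaks ties lexicographically", {
  grid <- enumerateGrid(ParameterBounds(100, 110, 3, 6))
  s <- makeSurface(grid, rep(1, nrow(grid)))
  opt <- bruteForceArgmax(s)
  expect_equal(opt$par[["x2"]], 100)
  expect_equal(opt$par[["x3"]], 3)

  # concave paraboloid centred on a grid point
  m <- -(grid$x2 - 105)^2 - (grid$x3 - 5)^2
  opt2 <- bruteForceArgmax(makeSurface(grid, m))
  expect_equal(opt2$par[["x2"]], 105)
  expect_equal(opt2$par[["x3"]], 5)
})

test_that("brute-force argmax equals a linear scan oracle", {
  set.seed(20)
  grid <- enumerateGrid(ParameterBounds(100, 124, 3, 22))
  m <- rnorm(nrow(grid))
  s <- makeSurface(grid, m)
  opt <- bruteForceArgmax(s)
  best <- which.max(m)
  expect_equal(opt$value, m[best])
  expect_equal(opt$par[["x2"]], grid$x2[best])
  expect_equal(opt$par[["x3"]], grid$x3[best])
  # missing points can never win
  s2 <- makeSurface(grid, m)
  s2@missing[best] <- TRUE
  expect_equal(bruteForceArgmax(s2)$value, max(m[-best]))
  s3 <- makeSurface(grid, m)
  s3@missing[] <- TRUE
  expect_error(bruteForceArgmax(s3), "no non-missing")
})

test_that("local maxima detection finds constructed peaks", {
  grid <- enumerateGrid(ParameterBounds(100, 200, 3, 30))
  peak <- function(c2, c3, h) h * exp(-((grid$x2 - c2)^2 / 200 +
                                        (grid$x3 - c3)^2 / 8))
  # single peak
  s1 <- makeSurface(grid, peak(150, 15, 1))
  expect_equal(nrow(findLocalMaxima(s1)), 1)
  # two equal peaks beyond the separation
  s2 <- makeSurface(grid, peak(120, 10, 1) + peak(180, 25, 1))
  m2 <- findLocalMaxima(s2, minSeparation = 3)
  expect_equal(nrow(m2), 2)
  # three Gaussians recovered within one grid step of their centres
  s3 <- makeSurface(grid, peak(120, 8, 1) + peak(160, 20, 0.9) +
                           peak(195, 12, 0.8))
  m3 <- findLocalMaxima(s3, minSeparation = 3)
  expect_equal(nrow(m3), 3)
  centers <- data.frame(x2 = c(120, 160, 195), x3 = c(8, 20, 12))
  for (i in 1:3) {
    d <- pmax(abs(m3$x2 - centers$x2[i]), abs(m3$x3 - centers$x3[i]))
    expect_lte(min(d), 1)
  }
  # sorted by descending value
  expect_true(!is.unsorted(-m3$value))
})

test_that("box narrowing contains all maxima and clips to bounds", {
  maxima <- data.frame(x2 = c(163, 166, 184), x3 = c(18, 15, 20))
  for (pad in c(0, 0.25, 0.5, 2)) {
    box <- narrowBox(maxima, pad)
    expect_true(all(maxima$x2 >= x2Range(box)[1] &
                    maxima$x2 <= x2Range(box)[2]))
    expect_true(all(maxima$x3 >= x3Range(box)[1] &
                    maxima$x3 <= x3Range(box)[2]))
  }
  # single maximum with no padding: degenerate 1x1 box
  single <- narrowBox(data.frame(x2 = 300, x3 = 12), 0)
  expect_equal(x2Range(single), c(300L, 300L))
  expect_equal(x3Range(single), c(12L, 12L))
  # outward rounding of fractional padding
  span <- narrowBox(data.frame(x2 = c(160, 180), x3 = c(15, 20)), 0.5)
  expect_equal(x2Range(span), c(150L, 190L))
  expect_equal(x3Range(span), c(12L, 23L))
  # clipped to the global bounds
  clip <- narrowBox(data.frame(x2 = c(110, 130), x3 = c(4, 29)), 1)
  expect_gte(x2Range(clip)[1], 100)
  expect_lte(x3Range(clip)[2], 30)
  # a minimum half-width keeps the box from collapsing
  wide <- narrowBox(data.frame(x2 = 300, x3 = 12), 0.5,
                    minHalfWidth = c(30, 1))
  expect_equal(x2Range(wide), c(270L, 330L))
  expect_equal(x3Range(wide), c(11L, 13L))
})

test_that("the bandwidth schedule halves per iteration, f divided by 3", {
  h0 <- Bandwidths(c(x2 = 30, x3 = 1))
  expect_equal(hValues(scheduleBandwidth(1, h0), "g"), c(x2 = 30, x3 = 1))
  expect_equal(hValues(scheduleBandwidth(2, h0), "g"), c(x2 = 15, x3 = 0.5))
  expect_equal(hValues(scheduleBandwidth(3, h0), "g"), c(x2 = 7.5, x3 = 0.25))
  for (it in 1:3)
    expect_equal(hValues(scheduleBandwidth(it, h0), "f"),
                 hValues(scheduleBandwidth(it, h0), "g") / 3)
  expect_equal(hValues(scheduleBandwidth(2, h0, factor = 0.1), "g"),
               c(x2 = 3, x3 = 0.1))
})

test_that("a noiseless objective converges immediately onto its optimum", {
  obj <- quadraticObjective(noiseSdG = 0, noiseSdF = 0)
  rep <- runPipeline(objectiveFunction(obj), nSims = c(800, 400, 400),
                     tolerance = 2, seed = 4)
  expect_true(rep@converged)
  expect_lte(length(iterations(rep)), 2)
  expect_lte(abs(optimum(rep)$par[["x2"]] - 400), 2)
  expect_lte(abs(optimum(rep)$par[["x3"]] - 15), 1)
})

test_that("pipeline bookkeeping: counts, nesting, bandwidths, feasibility", {
  obj <- quadraticObjective()
  schedule <- c(600, 300, 150)
  rep <- runPipeline(objectiveFunction(obj), nSims = schedule, tolerance = 0,
                     seed = 8)
  its <- iterations(rep)
  expect_equal(length(its), 3)
  expect_equal(vapply(its, function(s) s$nNew, numeric(1)), schedule)
  # records are accumulated, never discarded
  expect_equal(nrow(records(rep)), sum(schedule))
  # bandwidths strictly decreasing
  h2s <- vapply(its, function(s) hValues(s$bandwidths, "g")[["x2"]], numeric(1))
  expect_true(all(diff(h2s) < 0))
  # boxes stay inside the global bounds and the optimum inside its box
  for (s in its) {
    expect_true(x2Range(s$box)[1] >= 100 && x2Range(s$box)[2] <= 700)
    expect_true(s$optimum$par[["x2"]] >= x2Range(s$box)[1] &&
                s$optimum$par[["x2"]] <= x2Range(s$box)[2])
  }
  # final optimum is feasible under the global constraints
  opt <- optimum(rep)$par
  expect_true(isFeasible(opt[["x1"]], opt[["x2"]], opt[["x3"]]))
})

test_that("objective wrappers expose the simulator and synthetic surfaces", {
  params <- sampleParametrizations(3, ParameterBounds(50, 80, 3, 10),
                                   smallBudget(), seed = 2)
  fsim <- objectiveFunction(smallScheme(years = 2))
  v1 <- fsim(params, seed = 5)
  expect_named(v1, c("g", "f"))
  expect_equal(nrow(v1), 3)
  expect_identical(v1, fsim(params, seed = 5))

  fobj <- objectiveFunction(quadraticObjective())
  v2 <- fobj(params, seed = 5)
  expect_named(v2, c("g", "f"))
  expect_error(objectiveFunction(42), "SchemeConfig or a SyntheticObjective")
})
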