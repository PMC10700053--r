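test_that("synthetic records sit on the analytic surface when noiseless", {
  obj <- quadraticObjective(noiseSdG = 0, noiseSdF = 0)
  rec <- generateSyntheticRecords(obj, 100, seed = 1)
  truth <- 10 - 0.005 * (rec$x2 - 400)^2 - 0.5 * (rec$x3 - 15)^2
  expect_equal(rec$m, truth)
  expect_equal(rec$f, rep(0.02, 100))
  expect_identical(rec, generateSyntheticRecords(obj, 100, seed = 1))
})

test_that("synthetic noise has the configured scale", {
  obj <- quadraticObjective(noiseSdG = 0.5, noiseSdF = 0)
  rec <- generateSyntheticRecords(obj, 10000, seed = 2)
  resid <- rec$g - (10 - 0.005 * (rec$x2 - 400)^2 -
                      0.5 * (rec$x3 - 15)^2 + 50 * 0.02)
  seSd <- 0.5 / sqrt(2 * (10000 - 1))
  expect_lt(abs(sd(resid) - 0.5), 3 * seSd)
})

test_that("bootstrap comparison self-references to distance zero", {
  obj <- quadraticObjective()
  rec <- generateSyntheticRecords(obj, 400, seed = 3)
  grid <- enumerateGrid(stepX2 = 10L)
  nwOnly <- list(nw = function(r, g) smoothSurface(r, g))
  # subsample = full set is impossible with replacement to be the identity,
  # so pass the degenerate resample by using the full set as both draws:
  res <- bootstrapCompare(rec, methods = nwOnly, nBoot = 1,
                          subsampleSize = nrow(rec), grid = grid, seed = 4)
  # with a single draw the summary equals the replicate row
  expect_equal(res@summary$meanDistance, res@replicates$distance)

  # the reference surface scored on its own optimum gives distance 0
  ref <- res@reference
  expect_equal(unname(ref$optimum$par["x2"]),
               bruteForceArgmax(ref$surface)$par[["x2"]])

  # two identical methods produce identical metrics
  twin <- bootstrapCompare(rec, methods = list(a = nwOnly$nw, b = nwOnly$nw),
                           nBoot = 3, subsampleSize = 200, grid = grid,
                           seed = 5)
  a <- twin@summary[twin@summary$method == "a", -1]
  b <- twin@summary[twin@summary$method == "b", -1]
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("bootstrap metrics are invariant to record ordering", {
  obj <- quadraticObjective()
  rec <- generateSyntheticRecords(obj, 300, seed = 6)
  grid <- enumerateGrid(stepX2 = 10L)
  r1 <- bootstrapCompare(rec, nBoot = 3, subsampleSize = 150, grid = grid,
                         seed = 7)
  # reordering the records only relabels rows; the resample indices map to
  # the same multiset of records once the permutation is undone
  set.seed(1)
  perm <- sample(nrow(rec))
  recP <- rec[perm, ]
  # reference surface (all records) must be identical either way
  r2 <- bootstrapCompare(recP, nBoot = 3, subsampleSize = 150, grid = grid,
                         seed = 7)
  expect_equal(r1@reference$optimum$value, r2@reference$optimum$value)
  expect_equal(r1@reference$optimum$par, r2@reference$optimum$par)
})

test_that("a failing smoother is excluded and counted", {
  obj <- quadraticObjective()
  rec <- generateSyntheticRecords(obj, 200, seed = 8)
  grid <- enumerateGrid(stepX2 = 10L)
  boom <- function(r, g) stop("boom")
  res <- bootstrapCompare(rec, methods = list(nw = function(r, g)
    smoothSurface(r, g), bad = boom), nBoot = 4, subsampleSize = 100,
    grid = grid, seed = 9)
  expect_equal(res@nFailed, 4L)
  expect_true(all(res@replicates$method == "nw"))
})

test_that("optimum stability fractions behave at the edges", {
  obj <- quadraticObjective(noiseSdG = 0, noiseSdF = 0)
  grid <- enumerateGrid(stepX2 = 5L)
  region <- SearchBox(c(370, 430), c(13, 17))
  # noiseless: every repetition lands inside a region around the optimum
  # (finite samples still leave a little smoothing wobble in the argmax)
  st <- optimumStability(obj, sizes = c(400, 1000), nRep = 3, region = region,
                         grid = grid, seed = 10)
  expect_equal(st@fractions$fraction, c(1, 1))
  expect_named(st@density[[1]], c("grid", "density", "bandwidth"))

  # single repetition: the fraction is exactly 0 or 1
  noisy <- quadraticObjective()
  one <- optimumStability(noisy, sizes = 150, nRep = 1, region = region,
                          grid = grid, seed = 11)
  expect_true(one@fractions$fraction %in% c(0, 1))
})

test_that("subsample mode draws from a fixed record pool", {
  obj <- quadraticObjective()
  pool <- generateSyntheticRecords(obj, 1000, seed = 12)
  st <- optimumStability(pool, sizes = c(100, 400), nRep = 4,
                         region = SearchBox(c(385, 415), c(14, 16)),
                         grid = enumerateGrid(stepX2 = 10L), seed = 13)
  expect_equal(nrow(st@optima), 8)
  expect_true(all(st@fractions$fraction >= 0 & st@fractions$fraction <= 1))
  expect_error(optimumStability(pool, sizes = 2000, nRep = 1),
               "max.*sizes.*nrow|not TRUE")
})
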