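test_that("Mendelian sampling has mid-parent mean and half additive variance", {
  # zero-variance limit: offspring equals mid-parent exactly
  expect_equal(mendelianSample(2, 1, 0, 0, additiveVariance = 0), 1.5)
  # fully inbred parents: sampling variance collapses
  set.seed(1)
  x <- mendelianSample(rep(0, 500), rep(0, 500), 1 - 1e-12, 1 - 1e-12, 1)
  expect_lt(sd(x), 1e-5)
  # Monte-Carlo check of the stated variance sigma_a^2 / 2
  set.seed(2)
  draws <- mendelianSample(rep(0, 10000), rep(0, 10000), 0, 0, 1)
  seVar <- sqrt(2 / (10000 - 1)) * 0.5 # SE of a variance estimate, normal data
  expect_lt(abs(var(draws) - 0.5), 3 * seVar)
})

test_that("progeny-test accuracy follows the daughter-group formula", {
  expect_equal(progenyTestAccuracy(1, 1), 0.5)
  expect_gt(progenyTestAccuracy(1e7, 0.3), 0.999)
  # independent evaluation of the printed formula
  n <- 15; h2 <- 0.3
  expect_equal(progenyTestAccuracy(n, h2),
               sqrt((n * h2 / 4) / (1 + (n - 1) * h2 / 4)))
  # EBVs correlate with true values at the nominal accuracy
  set.seed(3)
  bv <- rnorm(20000)
  res <- progenyTestEBV(bv, 15, 0.3)
  expect_lt(abs(cor(res$ebv, bv) - res$accuracy), 0.02)
})

test_that("composite target applies the inbreeding weight and horizons", {
  expect_equal(compositeTarget(0, 0), 0)
  expect_equal(compositeTarget(12.2, 0), 12.2)
  expect_equal(compositeTarget(1.0, 0.022), -0.1)
  expect_equal(compositeTarget(5, 0.01, TargetSpec(inbreedingWeight = 0)), 5)
})

test_that("pedigree kinship matches closed forms and gene dropping", {
  founders <- data.frame(id = 1:4, sire_id = NA, dam_id = NA)
  expect_equal(pedigreeKinship(founders, 1:4), 0)
  # two full sibs from unrelated, non-inbred parents
  sibs <- rbind(founders,
                data.frame(id = 5:6, sire_id = 1, dam_id = 2))
  expect_equal(pedigreeKinship(sibs, 5:6), 0.25)
  # half sibs: 1/8
  half <- rbind(founders,
                data.frame(id = 5:6, sire_id = 1, dam_id = c(2, 3)))
  expect_equal(pedigreeKinship(half, 5:6), 0.125)
  # random 4-generation pedigree vs a gene-dropping estimate
  rp <- randomPedigree(nFounders = 8, nPerGen = 6, nGen = 4, seed = 9)
  exact <- pedigreeKinship(rp$ped, rp$cohort)
  mc <- geneDropKinship(rp$ped, rp$cohort, nDrops = 1e5, seed = 2)
  expect_lt(abs(exact - mc), 0.01)
})

test_that("cyclic or incomplete pedigrees are rejected", {
  cyc <- data.frame(id = 1:2, sire_id = c(2L, 1L), dam_id = NA_integer_)
  expect_error(kinshipMatrix(cyc), "cycle")
  orphan <- data.frame(id = 1L, sire_id = 99L, dam_id = NA_integer_)
  expect_error(kinshipMatrix(orphan), "not present")
  expect_error(pedigreeKinship(data.frame(id = 1, sire_id = NA, dam_id = NA),
                               ids = c(1, 2)), "missing")
})

test_that("scheme simulation is reproducible and internally consistent", {
  p <- c(x1 = 175, x2 = 100, x3 = 10)
  cfg <- smallScheme(years = 6)
  a <- simulateScheme(p, cfg, seed = 11)
  b <- simulateScheme(p, cfg, seed = 11)
  expect_identical(trajectories(a), trajectories(b))
  expect_identical(pedigree(a), pedigree(b))

  # the rolling kinship bookkeeping agrees exactly with the standalone
  # tabular method on the full pedigree
  ped <- pedigree(a)
  final <- ped$id[ped$birth_year == 6]
  expect_equal(inbreedingLevel(a), pedigreeKinship(ped, final))

  # founders are unrelated and non-inbred
  expect_equal(pedigreeKinship(ped, ped$id[ped$birth_year == 0]), 0)
  expect_true(all(ped$inbreeding_coeff[ped$birth_year == 0] == 0))

  # m is the composite of g and f
  expect_equal(targetValue(a),
               compositeTarget(geneticGain(a), inbreedingLevel(a)))
})

test_that("no additive variance means no genetic gain, every replicate", {
  p <- c(x1 = 175, x2 = 60, x3 = 5)
  for (s in 1:3) {
    out <- simulateScheme(p, SchemeConfig(years = 4, additiveVariance = 0),
                          seed = s)
    expect_identical(unname(trajectories(out)$g), rep(0, 4))
  }
})

test_that("infeasible designs are rejected", {
  expect_error(simulateScheme(c(x1 = 100, x2 = 10, x3 = 20)), "infeasible")
})

test_that("kinship accumulates over years in a closed population", {
  # average trajectory over replicates; expectation is non-decreasing
  traj <- rowMeans(sapply(1:10, function(s)
    trajectories(simulateScheme(c(x1 = 175, x2 = 60, x3 = 4),
                                smallScheme(years = 10), seed = s))$f))
  expect_true(all(diff(traj) > -1e-4))
  expect_gt(traj[10], traj[1])
})

test_that("record batches carry one derived seed per replicate", {
  params <- sampleParametrizations(4, ParameterBounds(50, 80, 3, 10),
                                   smallBudget(), seed = 5)
  rec <- simulateRecords(params, smallScheme(years = 3), seed = 99)
  expect_identical(names(rec),
                   c("replicate_id", "seed", "x1", "x2", "x3", "g", "f", "m"))
  expect_equal(rec$seed, deriveSeed(99, 1:4))
  expect_equal(rec$m, compositeTarget(rec$g, rec$f))
  # replicate 2 is reproducible in isolation from its own seed
  again <- simulateScheme(params[2, ], smallScheme(years = 3),
                          seed = rec$seed[2])
  expect_equal(targetValue(again), rec$m[2])
})
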