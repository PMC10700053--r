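# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Brute-force Nadaraya-Watson: plain double loop over queries and samples.
nwOracle <- function(query, points, y, h) {
  apply(query, 1, function(q) {
    w <- apply(points, 1, function(x)
      prod(exp(-((q - x) / h)^2 / 2) / sqrt(2 * pi)))
    sum(w * y) / sum(w)
  })
}

# Gene-dropping estimate of mean pairwise kinship of a cohort: founders get
# unique allele labels, alleles are dropped through the pedigree, and the
# kinship of (i, j) is the probability that one allele picked from each is
# identical by descent.
geneDropKinship <- function(ped, ids, nDrops = 1e5, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  si <- match(ped$sire_id, ped$id)
  di <- match(ped$dam_id, ped$id)
  A1 <- matrix(0L, nDrops, n)
  A2 <- matrix(0L, nDrops, n)
  nextAllele <- 1L
  for (i in seq_len(n)) {
    if (is.na(si[i])) { # founder
      A1[, i] <- nextAllele
      A2[, i] <- nextAllele + 1L
      nextAllele <- nextAllele + 2L
    } else {
      pick <- runif(nDrops) < 0.5
      A1[, i] <- ifelse(pick, A1[, si[i]], A2[, si[i]])
      pick <- runif(nDrops) < 0.5
      A2[, i] <- ifelse(pick, A1[, di[i]], A2[, di[i]])
    }
  }
  cols <- match(ids, ped$id)
  pairs <- utils::combn(cols, 2)
  ks <- apply(pairs, 2, function(p) {
    a <- p[1]; b <- p[2]
    mean((A1[, a] == A1[, b]) + (A1[, a] == A2[, b]) +
         (A2[, a] == A1[, b]) + (A2[, a] == A2[, b])) / 4
  })
  mean(ks)
}

# Monte-Carlo selection intensity: expected mean of the top k of n iid
# standard normals.
selectionIntensity <- function(k, n, nSim = 20000, seed = 1) {
  set.seed(seed)
  mean(replicate(nSim, mean(sort(rnorm(n), decreasing = TRUE)[1:k])))
}

# Random acyclic pedigree with founders in generation 0; returns the
# pedigree and the ids of the final generation.
randomPedigree <- function(nFounders = 8, nPerGen = 6, nGen = 4, seed = 1) {
  set.seed(seed)
  ped <- data.frame(id = seq_len(nFounders), sire_id = NA_integer_,
                    dam_id = NA_integer_)
  pool <- ped$id
  nextId <- nFounders + 1L
  for (g in seq_len(nGen)) {
    kids <- data.frame(
      id = seq.int(nextId, length.out = nPerGen),
      sire_id = sample(pool, nPerGen, replace = TRUE),
      dam_id = sample(pool, nPerGen, replace = TRUE))
    # avoid selfing: redraw dams equal to the sire
    same <- kids$sire_id == kids$dam_id
    while (any(same)) {
      kids$dam_id[same] <- sample(pool, sum(same), replace = TRUE)
      same <- kids$sire_id == kids$dam_id
    }
    ped <- rbind(ped, kids)
    pool <- kids$id
    nextId <- nextId + nPerGen
  }
  list(ped = ped, cohort = pool)
}

# Small scheme configuration used for simulator tests: a deliberately small
# herd so dozens of 15-year replicates run in seconds. The tested
# properties (selection response, kinship accumulation) are scale-free.
smallBudget <- function() BudgetModel(totalBudget = 1e6)
smallScheme <- function(years = 15) SchemeConfig(years = years)
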