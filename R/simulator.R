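# Stochastic simulation of a yearly progeny-testing dairy scheme under the
# infinitesimal model. One call = one realization of (g, f, m) for a design
# (x1 test daughters, x2 test bulls, x3 selected sires).

#' Mendelian sampling of an offspring breeding value
#'
#' Infinitesimal model: the offspring true breeding value is the mid-parent
#' value plus a Mendelian-sampling deviation
#' `e ~ Normal(0, additiveVariance * (1 - (F_sire + F_dam) / 2) / 2)`,
#' i.e. half the additive variance, shrunk by the mean parental inbreeding.
#'
#' @param bvSire,bvDam parental true breeding values (vectorized).
#' @param fSire,fDam parental inbreeding coefficients in `[0, 1)`.
#' @param additiveVariance additive genetic variance (>= 0).
#' @return offspring true breeding value(s); uses the current RNG stream.
#' @examples
#' set.seed(1)
#' mendelianSample(1, 0, 0, 0)
#' @export
mendelianSample <- function(bvSire, bvDam, fSire = 0, fDam = 0,
                            additiveVariance = 1) {
  stopifnot(additiveVariance >= 0, all(fSire >= 0 & fSire < 1),
            all(fDam >= 0 & fDam < 1))
  n <- max(length(bvSire), length(bvDam))
  v <- additiveVariance * (1 - (fSire + fDam) / 2) / 2
  (bvSire + bvDam) / 2 + rnorm(n, 0, sqrt(v))
}

#' Progeny-test estimated breeding value
#'
#' The accuracy of a sire EBV from the mean phenotype of `n` half-sib
#' daughters is `r = sqrt((n h2 / 4) / (1 + (n - 1) h2 / 4))`; the EBV is
#' drawn as `r^2 * bv + r * sqrt(1 - r^2) * sdA * z`, `z ~ N(0, 1)`, which
#' gives `corr(ebv, bv) = r` when `bv ~ N(0, sdA^2)`. With `n = 0` the EBV
#' is pure noise (`r = 0`).
#'
#' @param trueBV sire true breeding value(s).
#' @param nDaughters daughter group size (scalar, >= 0).
#' @param heritability narrow-sense heritability in (0, 1].
#' @param sdA additive genetic standard deviation of the candidate cohort.
#' @return list with `ebv` (vector) and `accuracy` (scalar r).
#' @examples
#' progenyTestAccuracy(15, 0.3)
#' @export
progenyTestEBV <- function(trueBV, nDaughters, heritability, sdA = 1) {
  r <- progenyTestAccuracy(nDaughters, heritability)
  ebv <- r^2 * trueBV + r * sqrt(1 - r^2) * sdA * rnorm(length(trueBV))
  list(ebv = ebv, accuracy = r)
}

#' @rdname progenyTestEBV
#' @export
progenyTestAccuracy <- function(nDaughters, heritability) {
  stopifnot(nDaughters >= 0, heritability > 0, heritability <= 1)
  q <- heritability / 4
  sqrt((nDaughters * q) / (1 + (nDaughters - 1) * q))
}

#' Full pedigree kinship matrix (tabular method)
#'
#' Recursive coancestry over a pedigree: founders are unrelated and
#' non-inbred; for an animal `i` with parents `(s, d)`,
#' `k(i, j) = (k(s, j) + k(d, j)) / 2` for any earlier `j`, and
#' `k(i, i) = (1 + k(s, d)) / 2`. Animals are processed in topological
#' order; a cyclic pedigree is an error.
#'
#' @param ped data.frame with columns `id`, `sire_id`, `dam_id`
#'   (`NA` = founder).
#' @return symmetric kinship matrix with `id` dimnames.
#' @export
kinshipMatrix <- function(ped) {
  n <- nrow(ped)
  idx <- match(ped$sire_id, ped$id)
  idy <- match(ped$dam_id, ped$id)
  if (any(is.na(idx) & !is.na(ped$sire_id)) ||
      any(is.na(idy) & !is.na(ped$dam_id)))
    stop("pedigree references parents that are not present")
  # topological levels: founders 0, child = max(parent levels) + 1
  level <- ifelse(is.na(idx) & is.na(idy), 0L, NA_integer_)
  for (pass in seq_len(n + 1L)) {
    unresolved <- which(is.na(level))
    if (!length(unresolved)) break
    if (pass > n) stop("cycle detected in pedigree")
    for (i in unresolved) {
      ls <- if (is.na(idx[i])) -1L else level[idx[i]]
      ld <- if (is.na(idy[i])) -1L else level[idy[i]]
      if (!is.na(ls) && !is.na(ld)) level[i] <- max(ls, ld) + 1L
    }
  }
  ord <- order(level, seq_len(n))
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in ord) {
    s <- idx[i]; d <- idy[i]
    prev <- ord[seq_len(match(i, ord) - 1L)]
    if (length(prev)) {
      ks <- if (is.na(s)) 0 else K[s, prev]
      kd <- if (is.na(d)) 0 else K[d, prev]
      K[i, prev] <- K[prev, i] <- (ks + kd) / 2
    }
    ksd <- if (is.na(s) || is.na(d)) 0 else K[s, d]
    K[i, i] <- (1 + ksd) / 2
  }
  K
}

#' Mean pairwise kinship of a cohort
#'
#' Mean coancestry over unordered distinct pairs of the given animals
#' (self-pairs excluded), computed with [kinshipMatrix()]. This is the
#' inbreeding level `f` of the cohort: the expected inbreeding of their
#' hypothetical offspring.
#'
#' @param ped pedigree data.frame (see [kinshipMatrix()]).
#' @param ids animal ids forming the cohort.
#' @return mean pairwise kinship (0 for a cohort of a single animal).
#' @export
pedigreeKinship <- function(ped, ids) {
  if (!all(ids %in% ped$id)) stop("cohort ids missing from the pedigree")
  K <- kinshipMatrix(ped)
  i <- match(ids, ped$id)
  n <- length(i)
  if (n < 2) return(0)
  S <- K[i, i, drop = FALSE]
  (sum(S) - sum(diag(S))) / (n * (n - 1))
}

#' Composite breeding target
#'
#' `m = sum_t w_t g_t - w_f * f`: with the default [TargetSpec-class]
#' (no horizon weights, `w_f = 50`) this is `m = g - 50 f`. For a
#' [SimOutcome-class] the optional horizon weights are applied to the
#' per-year gain trajectory.
#'
#' @param x a [SimOutcome-class], or a numeric vector of gains `g`.
#' @param f inbreeding level(s), required when `x` is numeric.
#' @param target a [TargetSpec-class].
#' @return composite target value(s).
#' @examples
#' compositeTarget(12.2, 0, TargetSpec())
#' compositeTarget(1.0, 0.022)
#' @export
compositeTarget <- function(x, f = NULL, target = TargetSpec()) {
  stopifnot(is(target, "TargetSpec"))
  w <- target@inbreedingWeight
  hw <- target@horizonWeights
  if (is(x, "SimOutcome")) {
    gain <- if (length(hw)) {
      yrs <- as.integer(names(hw))
      if (any(yrs < 1 | yrs > length(x@perYearG)))
        stop("horizonWeights refer to years outside the simulated range")
      sum(hw * x@perYearG[yrs])
    } else x@g
    return(gain - w * x@f)
  }
  if (is.null(f)) stop("f is required when x is a numeric gain")
  if (length(hw))
    stop("horizon weights need a full SimOutcome, not scalar g")
  x - w * f
}

#' Simulate the progeny-testing scheme once
#'
#' Runs `years` discrete cycles of the toy dairy scheme for one design
#' `(x1, x2, x3)`:
#' \enumerate{
#'   \item the `x3` highest-EBV bulls of the previous cohort are selected as
#'     sires (ties broken by lower id) and mated to dams drawn at random
#'     from cows of breeding age (2-5), producing `x2` bull calves and
#'     `round(damReplacement * founderCows)` replacement heifers;
#'   \item each bull calf receives `floor(x1 / x2)` test daughters, whose
#'     mean phenotype yields its EBV via [progenyTestEBV()] (daughter
#'     phenotypes are integrated out analytically, so test daughters do not
#'     enter the pedigree);
#'   \item newborn-cohort mean true breeding value and mean pairwise kinship
#'     are recorded each year, with kinship propagated exactly by the
#'     tabular method on a rolling matrix of all potential parents.
#' }
#' The outcome is bit-reproducible for fixed `(p, config, seed)`.
#'
#' @param p design: numeric `c(x1, x2, x3)` (named or positional), or a
#'   one-row data.frame with those columns.
#' @param config a [SchemeConfig-class].
#' @param target a [TargetSpec-class] used to compute `m`.
#' @param seed optional RNG seed.
#' @return a [SimOutcome-class].
#' @examples
#' out <- simulateScheme(c(x1 = 175, x2 = 100, x3 = 10),
#'                       SchemeConfig(years = 5), seed = 1)
#' geneticGain(out)
#' @export
simulateScheme <- function(p, config = SchemeConfig(), target = TargetSpec(),
                           seed = NULL) {
  if (is.data.frame(p)) p <- unlist(p[1, c("x1", "x2", "x3")])
  if (is.null(names(p))) names(p) <- c("x1", "x2", "x3")
  x1 <- as.integer(p[["x1"]]); x2 <- as.integer(p[["x2"]])
  x3 <- as.integer(p[["x3"]])
  if (x3 > x2) stop(sprintf("infeasible design: x3 = %d > x2 = %d", x3, x2))
  stopifnot(x1 >= 0, x2 >= 1, x3 >= 1)
  stopifnot(is(config, "SchemeConfig"), is(target, "TargetSpec"))

  withSeed(seed, {
    years <- config@years
    h2 <- config@heritability
    sdA <- sqrt(config@additiveVariance)
    nCow0 <- if (is.na(config@founderCows)) max(x1, 1L) else config@founderCows
    nBull0 <- if (is.na(config@founderBulls)) x2 else config@founderBulls
    nDaughters <- x1 %/% x2 # daughters per test bull; remainder discarded
    nHeifers <- max(1L, as.integer(round(config@damReplacement * nCow0)))

    # ---- founders -------------------------------------------------------
    nAct <- nCow0 + nBull0
    id <- seq_len(nAct)
    female <- c(rep(TRUE, nCow0), rep(FALSE, nBull0))
    age <- c(sample(2:5, nCow0, replace = TRUE), rep(1L, nBull0))
    bv <- rnorm(nAct, 0, sdA)
    Fcoef <- rep(0, nAct)
    ebv <- rep(NA_real_, nAct)
    ebv[!female] <- progenyTestEBV(bv[!female], nDaughters, h2, sdA)$ebv
    K <- diag(0.5, nAct)
    founderMean <- mean(bv)
    nextId <- nAct + 1L

    pedList <- vector("list", years + 1L)
    pedList[[1L]] <- data.frame(id = id, sire_id = NA_integer_,
                                dam_id = NA_integer_, sex = ifelse(female, "female", "male"),
                                birth_year = 0L, true_bv = bv, ebv = ebv,
                                inbreeding_coeff = 0)

    candidates <- which(!female) # current progeny-tested bull cohort
    perYearG <- perYearF <- sirePathG <- numeric(years)

    for (t in seq_len(years)) {
      # (1) truncation selection of sires on EBV, ties by lower id
      ord <- candidates[order(-ebv[candidates], id[candidates])]
      sires <- ord[seq_len(x3)]
      sirePathG[t] <- mean(bv[sires])

      # (2) matings: dams at random among cows of breeding age
      eligible <- which(female & age >= 2L & age <= 5L)
      if (!length(eligible)) stop("no cows of breeding age left to mate")
      nCalves <- x2 + nHeifers
      dams <- if (length(eligible) >= nCalves) sample(eligible, nCalves)
              else sample(eligible, nCalves, replace = TRUE)
      sireOf <- sires[sample.int(x3, nCalves, replace = TRUE)]

      Fnew <- K[cbind(sireOf, dams)]
      bvNew <- mendelianSample(bv[sireOf], bv[dams], Fcoef[sireOf],
                               Fcoef[dams], config@additiveVariance)
      femaleNew <- c(rep(FALSE, x2), rep(TRUE, nHeifers))
      idNew <- seq.int(nextId, length.out = nCalves)
      nextId <- nextId + nCalves

      # (3) progeny-test EBVs for the new bull cohort
      ebvNew <- rep(NA_real_, nCalves)
      ebvNew[!femaleNew] <- progenyTestEBV(bvNew[!femaleNew], nDaughters,
                                           h2, sdA)$ebv

      # (4) kinship bookkeeping: rows of newborns vs active animals, then
      # newborn vs newborn via their (already-active) parents
      R <- 0.5 * (K[sireOf, , drop = FALSE] + K[dams, , drop = FALSE])
      NN <- 0.5 * (R[, sireOf, drop = FALSE] + R[, dams, drop = FALSE])
      diag(NN) <- 0.5 * (1 + Fnew)

      perYearG[t] <- mean(bvNew) - founderMean
      perYearF[t] <- if (nCalves > 1)
        (sum(NN) - sum(diag(NN))) / (nCalves * (nCalves - 1)) else 0

      pedList[[t + 1L]] <- data.frame(id = idNew, sire_id = id[sireOf],
                                      dam_id = id[dams],
                                      sex = ifelse(femaleNew, "female", "male"),
                                      birth_year = t, true_bv = bvNew,
                                      ebv = ebvNew, inbreeding_coeff = Fnew)

      # (5) append newborns, age the herd, drop animals that can no longer
      # become parents (spent sires and culled cows); their genetic
      # contribution is already embedded in descendant kinship rows
      K <- rbind(cbind(K, t(R)), cbind(R, NN))
      id <- c(id, idNew)
      female <- c(female, femaleNew)
      age <- c(age, rep(0L, nCalves))
      bv <- c(bv, bvNew)
      Fcoef <- c(Fcoef, Fnew)
      ebv <- c(ebv, ebvNew)
      newborn <- seq.int(length(id) - nCalves + 1L, length(id))
      candidates <- newborn[!femaleNew]

      if (t < years) {
        age <- age + 1L
        keep <- (female & age <= 5L) | (seq_along(id) %in% candidates)
        K <- K[keep, keep, drop = FALSE]
        id <- id[keep]; female <- female[keep]; age <- age[keep]
        bv <- bv[keep]; Fcoef <- Fcoef[keep]; ebv <- ebv[keep]
        candidates <- which(!female & age == 1L)
      }
    }

    ped <- do.call(rbind, pedList)
    rownames(ped) <- NULL
    out <- new("SimOutcome", g = perYearG[years], f = perYearF[years],
               m = 0, perYearG = perYearG, perYearF = perYearF,
               sirePathG = sirePathG, pedigree = ped,
               params = c(x1 = x1, x2 = x2, x3 = x3))
    out@m <- compositeTarget(out, target = target)
    out
  })
}

#' Simulate a batch of designs into a record table
#'
#' Evaluates [simulateScheme()] once per row of `params`, using one derived
#' RNG stream per replicate (see [deriveSeed()]), and returns the standard
#' record table.
#'
#' @param params data.frame with columns x1, x2, x3.
#' @param config a [SchemeConfig-class].
#' @param target a [TargetSpec-class].
#' @param seed global seed from which per-replicate seeds are derived.
#' @return data.frame with columns replicate_id, seed, x1, x2, x3, g, f, m.
#' @export
simulateRecords <- function(params, config = SchemeConfig(),
                            target = TargetSpec(), seed = 1L) {
  n <- nrow(params)
  seeds <- deriveSeed(seed, seq_len(n))
  res <- lapply(seq_len(n), function(i) {
    out <- simulateScheme(params[i, ], config, target, seed = seeds[i])
    c(g = out@g, f = out@f, m = out@m)
  })
  res <- do.call(rbind, res)
  data.frame(replicate_id = seq_len(n), seed = seeds,
             x1 = params$x1, x2 = params$x2, x3 = params$x3,
             g = res[, "g"], f = res[, "f"], m = res[, "m"])
}
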