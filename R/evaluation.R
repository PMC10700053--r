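# Meta-analyses of the optimization pipeline: bootstrap comparison of
# smoothing methods and optimum-location stability versus the number of
# simulations, plus the synthetic objective generator that makes both
# testable without the full breeding simulator.

#' Construct a synthetic objective
#'
#' @param gFun,fFun vectorized functions of (x2, x3) giving the noiseless
#'   gain and inbreeding surfaces.
#' @param noiseSdG,noiseSdF Gaussian realization noise standard deviations.
#' @param argmax true `c(x2, x3)` argmax of the implied composite target.
#' @param label short description.
#' @return a [SyntheticObjective-class].
#' @export
syntheticObjective <- function(gFun, fFun, noiseSdG = 1, noiseSdF = 0.004,
                               argmax, label = "custom") {
  new("SyntheticObjective", gFun = gFun, fFun = fFun, noiseSdG = noiseSdG,
      noiseSdF = noiseSdF, argmax = as.numeric(argmax), label = label)
}

#' Default quadratic test objective with a known optimum
#'
#' A concave paraboloid in the (x2, x3) plane,
#' `m*(x2, x3) = height - a (x2 - c2)^2 - b (x3 - c3)^2`, realized through
#' `g = m* + w * fLevel + noise` and a flat inbreeding surface
#' `f = fLevel + noise`, so the composite `g - w f` has its argmax exactly
#' at `center`. Default curvatures make one grid step in `x3` worth about
#' half a realization SD near the optimum, with `x2` far flatter per unit
#' -- mirroring the roughly 20-fold scale difference between the two
#' decision variables -- so the optimum is identifiable at realistic
#' simulation budgets while single realizations stay dominated by noise.
#'
#' @param center true optimum `c(x2, x3)`.
#' @param curvature `c(a, b)` quadratic coefficients per x2^2 and x3^2.
#' @param height peak value of the composite target.
#' @param fLevel baseline inbreeding level.
#' @param noiseSdG,noiseSdF realization noise standard deviations.
#' @param inbreedingWeight weight `w` used to embed `fLevel` in `g`.
#' @return a [SyntheticObjective-class].
#' @examples
#' obj <- quadraticObjective()
#' trueArgmax(obj)
#' @export
quadraticObjective <- function(center = c(400, 15),
                               curvature = c(0.005, 0.5), height = 10,
                               fLevel = 0.02, noiseSdG = 1, noiseSdF = 0.004,
                               inbreedingWeight = 50) {
  force(center); force(curvature); force(height); force(fLevel)
  w <- inbreedingWeight
  gFun <- function(x2, x3)
    height - curvature[1] * (x2 - center[1])^2 -
      curvature[2] * (x3 - center[2])^2 + w * fLevel
  fFun <- function(x2, x3) rep(fLevel, length(x2))
  syntheticObjective(gFun, fFun, noiseSdG, noiseSdF, argmax = center,
                     label = "concave quadratic")
}

#' Generate noisy records from a synthetic objective
#'
#' Samples designs as [sampleParametrizations()] does and attaches noisy
#' realizations `g = gFun + noise`, `f = max(0, fFun + noise)` and the
#' composite `m`.
#'
#' @param obj a [SyntheticObjective-class].
#' @param n number of records.
#' @param bounds,budget sampling region, as in [sampleParametrizations()].
#' @param target [TargetSpec-class] for the composite.
#' @param seed RNG seed (reproducible).
#' @return record data.frame (replicate_id, seed, x1, x2, x3, g, f, m).
#' @export
generateSyntheticRecords <- function(obj, n, bounds = ParameterBounds(),
                                     budget = BudgetModel(),
                                     target = TargetSpec(), seed = 1L) {
  stopifnot(is(obj, "SyntheticObjective"), n >= 1)
  withSeed(seed, {
    params <- sampleParametrizations(n, bounds, budget)
    g <- obj@gFun(params$x2, params$x3) + rnorm(n, 0, obj@noiseSdG)
    f <- pmax(0, obj@fFun(params$x2, params$x3) + rnorm(n, 0, obj@noiseSdF))
    data.frame(replicate_id = seq_len(n), seed = seed, params,
               g = g, f = f, m = compositeTarget(g, f, target))
  })
}

#' Bootstrap comparison of smoothing methods
#'
#' Draws `nBoot` bootstrap subsamples (with replacement) from the record
#' set; each method smooths the subsample, its argmax is taken, and the
#' suggested optimum is scored against the reference surface built from
#' *all* records (by default the kernel-regression estimate on the full
#' set): the target value the reference assigns to the suggestion, and the
#' Euclidean distance in the (x2, x3) plane from the reference optimum
#' (optionally weighted per dimension, since x2 and x3 scales differ by
#' roughly 20x). A method failing on a draw is recorded and excluded.
#'
#' @param rec full record data.frame.
#' @param methods named list of smoothers `function(rec, grid) ->`
#'   [KernelSurface-class]; default Nadaraya-Watson vs linear baseline.
#' @param nBoot number of bootstrap draws.
#' @param subsampleSize size of each draw.
#' @param grid evaluation grid (default: full default-bounds grid).
#' @param bandwidths [Bandwidths-class] for the default NW smoother and the
#'   reference surface.
#' @param target [TargetSpec-class].
#' @param distWeight `c(wx2, wx3)` per-dimension distance weights.
#' @param seed RNG seed; draws are derived deterministically from it.
#' @return a [ComparisonResult-class].
#' @export
bootstrapCompare <- function(rec, methods = NULL, nBoot = 100,
                             subsampleSize = nrow(rec) %/% 2,
                             grid = enumerateGrid(),
                             bandwidths = Bandwidths(),
                             target = TargetSpec(),
                             distWeight = c(1, 1), seed = 1L) {
  stopifnot(nBoot >= 1, subsampleSize >= 1, subsampleSize <= nrow(rec))
  if (is.null(methods))
    methods <- list(
      nw = function(r, g) smoothSurface(r, g, bandwidths, target),
      linear = function(r, g) linearBaselineSurface(r, g, target))
  stopifnot(length(methods) >= 1, !is.null(names(methods)))

  reference <- smoothSurface(rec, grid, bandwidths, target)
  refOpt <- bruteForceArgmax(reference)
  refLookup <- reference@mHat
  key <- paste(grid$x2, grid$x3)

  rows <- list(); nFailed <- 0L
  for (b in seq_len(nBoot)) {
    idx <- withSeed(deriveSeed(seed, b),
                    sample.int(nrow(rec), subsampleSize, replace = TRUE))
    sub <- rec[idx, ]
    for (meth in names(methods)) {
      res <- tryCatch({
        surf <- methods[[meth]](sub, grid)
        opt <- bruteForceArgmax(surf)
        refVal <- refLookup[match(paste(opt$par["x2"], opt$par["x3"]), key)]
        dist <- sqrt((distWeight[1] * (opt$par[["x2"]] - refOpt$par[["x2"]]))^2 +
                     (distWeight[2] * (opt$par[["x3"]] - refOpt$par[["x3"]]))^2)
        data.frame(draw = b, method = meth, x2 = opt$par[["x2"]],
                   x3 = opt$par[["x3"]], refValue = refVal, distance = dist)
      }, error = function(e) NULL)
      if (is.null(res)) nFailed <- nFailed + 1L else rows[[length(rows) + 1L]] <- res
    }
  }
  repl <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(repl, repl$method), function(d)
    data.frame(method = d$method[1], meanRefValue = mean(d$refValue),
               meanDistance = mean(d$distance), n = nrow(d))))
  summary <- summary[order(match(summary$method, names(methods))), ]
  rownames(summary) <- NULL
  new("ComparisonResult", summary = summary, replicates = repl,
      nFailed = nFailed,
      reference = list(surface = reference, optimum = refOpt))
}

#' Optimum-location stability versus number of simulations
#'
#' For each sample size, repeatedly builds a record set (freshly generated
#' from a [SyntheticObjective-class], or subsampled without replacement
#' from a supplied record pool), smooths it and takes the argmax. Returns
#' all estimated optima, the fraction falling inside a reference region,
#' and a product-Gaussian kernel density summary of the optimum locations
#' over the (x2, x3) plane (Scott's plug-in bandwidth
#' `sigma_d * n^(-1/6)`).
#'
#' @param x a [SyntheticObjective-class] (fresh mode) or record data.frame
#'   (subsample mode).
#' @param sizes vector of record-set sizes.
#' @param nRep repetitions per size.
#' @param region reference [SearchBox-class] the fractions refer to.
#' @param bounds,budget sampling region for fresh generation.
#' @param grid evaluation grid.
#' @param bandwidths [Bandwidths-class] for smoothing.
#' @param target [TargetSpec-class].
#' @param seed RNG seed.
#' @return a [StabilityResult-class].
#' @export
optimumStability <- function(x, sizes, nRep = 50,
                             region = SearchBox(c(130, 210), c(15, 21)),
                             bounds = ParameterBounds(),
                             budget = BudgetModel(), grid = enumerateGrid(),
                             bandwidths = Bandwidths(), target = TargetSpec(),
                             seed = 1L) {
  stopifnot(all(sizes >= 1), nRep >= 1, is(region, "SearchBox"))
  fresh <- is(x, "SyntheticObjective")
  if (!fresh) stopifnot(is.data.frame(x), max(sizes) <= nrow(x))
  rows <- list()
  for (si in seq_along(sizes)) {
    size <- sizes[si]
    for (r in seq_len(nRep)) {
      s <- deriveSeed(seed, si * 100000L + r)
      rec <- if (fresh) {
        generateSyntheticRecords(x, size, bounds, budget, target, seed = s)
      } else {
        x[withSeed(s, sample.int(nrow(x), size)), ]
      }
      opt <- bruteForceArgmax(smoothSurface(rec, grid, bandwidths, target))
      rows[[length(rows) + 1L]] <-
        data.frame(size = size, rep = r, x2 = opt$par[["x2"]],
                   x3 = opt$par[["x3"]], value = opt$value)
    }
  }
  optima <- do.call(rbind, rows)
  inside <- optima$x2 >= x2Range(region)[1] & optima$x2 <= x2Range(region)[2] &
            optima$x3 >= x3Range(region)[1] & optima$x3 <= x3Range(region)[2]
  fractions <- do.call(rbind, lapply(split(inside, optima$size), function(z)
    data.frame(n = length(z), fraction = mean(z))))
  fractions <- data.frame(size = as.numeric(rownames(fractions)), fractions)
  fractions <- fractions[order(fractions$size), ]
  rownames(fractions) <- NULL
  density <- lapply(split(optima, optima$size), function(d)
    optimaDensity(d$x2, d$x3, bounds))
  new("StabilityResult", optima = optima, fractions = fractions,
      density = density, region = region)
}

# Product-Gaussian KDE of optimum locations on a coarse (x2, x3) grid,
# Scott's plug-in bandwidth per dimension (floored at one grid unit).
optimaDensity <- function(x2, x3, bounds, gridSize = 60L) {
  n <- length(x2)
  h2 <- max(stats::sd(x2) * n^(-1 / 6), 1, na.rm = TRUE)
  h3 <- max(stats::sd(x3) * n^(-1 / 6), 1, na.rm = TRUE)
  gx <- seq(x2Range(bounds)[1], x2Range(bounds)[2], length.out = gridSize)
  gy <- seq(x3Range(bounds)[1], x3Range(bounds)[2], length.out = gridSize)
  gr <- expand.grid(x2 = gx, x3 = gy)
  w2 <- outer(gr$x2, x2, function(a, b) gaussianKernel((a - b) / h2)) / h2
  w3 <- outer(gr$x3, x3, function(a, b) gaussianKernel((a - b) / h3)) / h3
  dens <- rowMeans(w2 * w3)
  list(grid = gr, density = dens, bandwidth = c(x2 = h2, x3 = h3))
}
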