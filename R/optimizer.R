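# Maximization of the smoothed target surface: brute-force argmax,
# grid-local-maxima detection, search-box narrowing, the bandwidth halving
# schedule, and the full iterative narrow-and-refine pipeline.

#' Brute-force argmax of a smoothed surface
#'
#' The grid point with the maximal composite estimate among non-missing
#' points; ties are broken lexicographically by `(x2, x3)`.
#'
#' @param surface a [KernelSurface-class].
#' @param response which estimate to maximize ("m", "g" or "f" -- "f" is
#'   minimized-in-spirit analyses should negate it themselves).
#' @return list with `par` (named integer c(x1, x2, x3)) and `value`.
#' @export
bruteForceArgmax <- function(surface, response = c("m", "g", "f")) {
  response <- match.arg(response)
  est <- switch(response, m = surface@mHat, g = surface@gHat, f = surface@fHat)
  ok <- !surface@missing & is.finite(est)
  if (!any(ok)) stop("surface has no non-missing estimates")
  grid <- surface@grid
  ord <- order(grid$x2, grid$x3)
  est <- est[ord]; ok <- ok[ord]; grid <- grid[ord, ]
  best <- which(ok)[which.max(est[ok])] # which.max returns the first max
  par <- c(x1 = if ("x1" %in% names(grid)) as.integer(grid$x1[best]) else NA_integer_,
           x2 = as.integer(grid$x2[best]), x3 = as.integer(grid$x3[best]))
  list(par = par, value = est[best])
}

#' Local maxima of a surface on a full rectangular grid
#'
#' Grid points whose estimate is >= all of their (up to) 8 neighbors.
#' Missing neighbors do not block a maximum; missing points cannot be
#' maxima. Among maxima closer than `minSeparation` (Chebyshev distance in
#' grid steps) only the highest is kept. Returned sorted by descending value.
#'
#' @param surface a [KernelSurface-class] whose grid is a full rectangle of
#'   `(x2, x3)` combinations.
#' @param minSeparation minimal separation between reported maxima, in grid
#'   steps (0 = report all).
#' @return data.frame with columns x2, x3, value.
#' @export
findLocalMaxima <- function(surface, minSeparation = 0) {
  grid <- surface@grid
  xs <- sort(unique(grid$x2)); ys <- sort(unique(grid$x3))
  if (nrow(grid) != length(xs) * length(ys))
    stop("grid must be a full rectangle of (x2, x3) combinations")
  M <- matrix(-Inf, length(xs), length(ys))
  i <- match(grid$x2, xs); j <- match(grid$x3, ys)
  val <- ifelse(surface@missing, NA_real_, surface@mHat)
  M[cbind(i, j)] <- val
  nx <- length(xs); ny <- length(ys)
  cmp <- matrix(TRUE, nx, ny)
  shifts <- expand.grid(dx = -1:1, dy = -1:1)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0), ]
  for (k in seq_len(nrow(shifts))) {
    dx <- shifts$dx[k]; dy <- shifts$dy[k]
    N <- matrix(-Inf, nx, ny)
    xi <- seq_len(nx) + dx; yi <- seq_len(ny) + dy
    okx <- xi >= 1 & xi <= nx; oky <- yi >= 1 & yi <= ny
    N[okx, oky] <- M[xi[okx], yi[oky]]
    N[is.na(N)] <- -Inf # a missing neighbor does not block
    cmp <- cmp & (is.na(M) | M >= N)
  }
  isMax <- cmp & !is.na(M)
  idx <- which(isMax, arr.ind = TRUE)
  out <- data.frame(x2 = xs[idx[, 1]], x3 = ys[idx[, 2]],
                    value = M[idx])
  out <- out[order(-out$value, out$x2, out$x3), ]
  rownames(out) <- NULL
  if (minSeparation > 0 && nrow(out) > 1) {
    sx <- if (length(xs) > 1) min(diff(xs)) else 1
    sy <- if (length(ys) > 1) min(diff(ys)) else 1
    keep <- logical(nrow(out))
    for (r in seq_len(nrow(out))) {
      kept <- which(keep)
      if (!length(kept)) { keep[r] <- TRUE; next }
      d <- pmax(abs(out$x2[kept] - out$x2[r]) / sx,
                abs(out$x3[kept] - out$x3[r]) / sy)
      keep[r] <- all(d >= minSeparation)
    }
    out <- out[keep, ]
    rownames(out) <- NULL
  }
  out
}

#' Narrow the search box around current local maxima
#'
#' The smallest box containing all maxima, expanded on each side by
#' `paddingFraction` of its own span in that dimension, rounded outward
#' (floor below, ceiling above) and clipped to the global bounds. Always
#' contains every input maximum.
#'
#' @param maxima data.frame with columns x2, x3 (e.g. from
#'   [findLocalMaxima()]).
#' @param paddingFraction non-negative expansion fraction (default 0.5).
#' @param bounds global [ParameterBounds-class] to clip to.
#' @param minHalfWidth `c(x2, x3)` minimum half-width of the box around the
#'   maxima-box center (default 0, i.e. no minimum). The pipeline passes a
#'   multiple of the current bandwidth here, since a kernel argmax cannot be
#'   localized more finely than the smoothing window: a single sharp maximum
#'   would otherwise collapse the box to one point.
#' @return a [SearchBox-class].
#' @examples
#' narrowBox(data.frame(x2 = c(163, 166, 184), x3 = c(18, 15, 20)))
#' @export
narrowBox <- function(maxima, paddingFraction = 0.5,
                      bounds = ParameterBounds(),
                      minHalfWidth = c(0, 0)) {
  stopifnot(nrow(maxima) >= 1, paddingFraction >= 0, all(minHalfWidth >= 0))
  pad <- function(v, lim, mhw) {
    lo <- min(v); hi <- max(v); p <- paddingFraction * (hi - lo)
    ctr <- (lo + hi) / 2
    lo <- min(lo - p, ctr - mhw); hi <- max(hi + p, ctr + mhw)
    c(max(lim[1], floor(lo)), min(lim[2], ceiling(hi)))
  }
  SearchBox(pad(maxima$x2, x2Range(bounds), minHalfWidth[1]),
            pad(maxima$x3, x3Range(bounds), minHalfWidth[2]))
}

#' Bandwidth halving schedule
#'
#' Bandwidths for iteration `k`: `h = h0 * factor^(k - 1)` per dimension,
#' with the `f` response scaling preserved across iterations. The default
#' schedule starting from `h0 = (x2: 30, x3: 1)` with halving gives
#' `(30, 1) -> (15, 0.5) -> (7.5, 0.25)`.
#'
#' @param iteration 1-based iteration index.
#' @param h0 initial [Bandwidths-class].
#' @param factor shrink factor per iteration, in (0, 1).
#' @return a [Bandwidths-class].
#' @examples
#' hValues(scheduleBandwidth(3, Bandwidths()))
#' @export
scheduleBandwidth <- function(iteration, h0 = Bandwidths(), factor = 0.5) {
  stopifnot(iteration >= 1, factor > 0, factor < 1)
  Bandwidths(h = hValues(h0, "g") * factor^(iteration - 1),
             fScale = h0@fScale)
}

#' Iterative narrow-and-refine optimization pipeline
#'
#' The full loop: sample designs uniformly in the current search box,
#' evaluate the stochastic objective on them, smooth gain and inbreeding
#' over the in-box grid using *all* accumulated records (records outside
#' the current box still carry kernel weight near its boundary, which
#' mitigates edge bias), compose the target surface, take the brute-force
#' argmax and the local maxima, narrow the box around them, and shrink the
#' bandwidth. Stops when the optimum's `(x2, x3)` moves by at most
#' `tolerance` grid steps in each dimension between consecutive iterations,
#' or after `maxIterations`.
#'
#' @param objective function `(params, seed) -> data.frame(g, f)` evaluated
#'   once per design row; see [objectiveFunction()] for the two built-in
#'   objectives (breeding simulator and synthetic test surface).
#' @param bounds global [ParameterBounds-class].
#' @param budget [BudgetModel-class] for daughter allocation.
#' @param target [TargetSpec-class].
#' @param h0 initial [Bandwidths-class].
#' @param nSims number of new simulations per iteration (recycled if fewer
#'   entries than iterations); the default mirrors a heavy first iteration
#'   followed by cheaper refinements.
#' @param factor bandwidth shrink factor per iteration.
#' @param paddingFraction box expansion fraction for [narrowBox()].
#' @param tolerance convergence tolerance in grid steps per dimension.
#' @param maxIterations maximum number of iterations.
#' @param minSeparation separation for [findLocalMaxima()] (grid steps).
#' @param nMaximaKeep number of top local maxima used to narrow the box.
#' @param gridStep `c(x2, x3)` grid steps for surface evaluation.
#' @param massFloor weight-mass underflow floor, see [nwEstimate()].
#' @param seed global seed; per-iteration sampling and objective seeds are
#'   derived from it.
#' @return an [OptimizationReport-class].
#' @export
runPipeline <- function(objective, bounds = ParameterBounds(),
                        budget = BudgetModel(), target = TargetSpec(),
                        h0 = Bandwidths(), nSims = c(2000, 1500, 500),
                        factor = 0.5, paddingFraction = 0.5, tolerance = 1,
                        maxIterations = length(nSims), minSeparation = 3,
                        nMaximaKeep = 3, gridStep = c(1, 1), massFloor = 1e-3,
                        seed = 1L) {
  stopifnot(is.function(objective), maxIterations >= 1)
  box <- SearchBox(x2Range(bounds), x3Range(bounds))
  allRec <- NULL
  iters <- list()
  converged <- FALSE
  reason <- "maximum number of iterations reached"
  prevOpt <- NULL

  for (it in seq_len(maxIterations)) {
    nNew <- nSims[min(it, length(nSims))]
    h <- scheduleBandwidth(it, h0, factor)
    sampSeed <- deriveSeed(seed, 1000L + it)
    params <- sampleParametrizations(nNew, boxToBounds(box), budget,
                                     seed = sampSeed)
    objSeed <- deriveSeed(seed, 2000L + it)
    vals <- objective(params, objSeed)
    if (!all(c("g", "f") %in% names(vals)))
      stop(sprintf("objective failed to return g and f in iteration %d", it))
    rec <- data.frame(replicate_id = seq_len(nrow(params)) +
                        if (is.null(allRec)) 0L else nrow(allRec),
                      seed = objSeed, params, g = vals$g, f = vals$f)
    rec$m <- compositeTarget(rec$g, rec$f, target)
    allRec <- rbind(allRec, rec)

    grid <- enumerateGrid(boxToBounds(box), budget,
                          stepX2 = gridStep[1], stepX3 = gridStep[2])
    surf <- smoothSurface(allRec, grid, h, target, massFloor = massFloor)
    opt <- bruteForceArgmax(surf)
    maxima <- findLocalMaxima(surf, minSeparation = minSeparation)
    maxima <- head(maxima, nMaximaKeep)

    iters[[it]] <- list(index = it, box = box, bandwidths = h, nNew = nNew,
                        optimum = opt, maxima = maxima)

    if (!is.null(prevOpt)) {
      moved <- c(abs(opt$par["x2"] - prevOpt$par["x2"]) / gridStep[1],
                 abs(opt$par["x3"] - prevOpt$par["x3"]) / gridStep[2])
      if (all(moved <= tolerance)) {
        converged <- TRUE
        reason <- sprintf("optimum stable within %g grid step(s) at iteration %d",
                          tolerance, it)
        prevOpt <- opt
        break
      }
    }
    prevOpt <- opt
    if (it < maxIterations)
      box <- narrowBox(maxima, paddingFraction, bounds,
                       minHalfWidth = 2 * hValues(h, "g"))
  }

  new("OptimizationReport", iterations = iters, optimum = prevOpt,
      converged = converged, reason = reason, records = allRec)
}

#' Built-in stochastic objectives for the pipeline
#'
#' Wraps either the breeding-scheme simulator or a
#' [SyntheticObjective-class] into the `(params, seed)` interface
#' [runPipeline()] expects, so the pipeline runs identically against both.
#'
#' @param x a [SchemeConfig-class] (breeding simulator) or a
#'   [SyntheticObjective-class] (analytic test surface).
#' @param target a [TargetSpec-class] (used by the simulator wrapper).
#' @return function `(params, seed) -> data.frame(g, f)`.
#' @export
objectiveFunction <- function(x, target = TargetSpec()) {
  if (is(x, "SchemeConfig")) {
    function(params, seed) {
      rec <- simulateRecords(params, x, target, seed = seed)
      rec[, c("g", "f")]
    }
  } else if (is(x, "SyntheticObjective")) {
    function(params, seed) {
      withSeed(seed, {
        g <- x@gFun(params$x2, params$x3) + rnorm(nrow(params), 0, x@noiseSdG)
        f <- pmax(0, x@fFun(params$x2, params$x3) +
                       rnorm(nrow(params), 0, x@noiseSdF))
        data.frame(g = g, f = f)
      })
    }
  } else stop("x must be a SchemeConfig or a SyntheticObjective")
}
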