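# Kernel regression of noisy simulation records over the design grid,
# the piecewise-linear interpolation baseline, and bandwidth selection.

#' Standard Gaussian kernel
#'
#' `K(u) = (2*pi)^(-1/2) * exp(-u^2 / 2)`: strictly positive, symmetric,
#' integrates to one. Multivariate smoothing uses the product of independent
#' one-dimensional components, `K(u1, u2, u3) = K(u1) K(u2) K(u3)`.
#'
#' @param u standardized distance (vectorized).
#' @return kernel weight(s).
#' @examples
#' gaussianKernel(0)  # 1 / sqrt(2 * pi)
#' @export
gaussianKernel <- function(u) {
  exp(-u^2 / 2) / sqrt(2 * pi)
}

# Expected total kernel mass at an interior query if the n samples were
# uniform over their bounding box: n * prod(h_d / range_d), with the
# per-dimension factor capped at K(0) (a sample cannot contribute more).
expectedUniformMass <- function(points, h) {
  n <- nrow(points)
  fac <- vapply(seq_along(h), function(d) {
    r <- diff(range(points[, d]))
    if (r > 0) min(h[d] / r, gaussianKernel(0)) else gaussianKernel(0)
  }, numeric(1))
  n * prod(fac)
}

#' Nadaraya-Watson estimate at query points
#'
#' The locally weighted average
#' `sum_i y_i * prod_d K((q_d - x_{i,d}) / h_d) / sum_i prod_d K(...)`.
#' Estimates whose total kernel weight mass falls below
#' `massFloor * (expected mass under uniformly spread samples)` are flagged
#' missing (`NA`) rather than extrapolated: far outside the sampled region
#' the weighted average is dominated by a handful of distant samples and is
#' not a meaningful estimate.
#'
#' @param query numeric matrix (or data.frame) of query coordinates, one row
#'   per query.
#' @param points numeric matrix of sample coordinates (same columns).
#' @param y numeric responses, one per sample row.
#' @param h positive bandwidth per coordinate dimension.
#' @param massFloor relative weight-mass underflow floor (default 1e-3);
#'   set to 0 to disable flagging.
#' @return list with `estimate`, `mass` and logical `missing`, each of
#'   length `nrow(query)`.
#' @examples
#' s <- matrix(runif(40), ncol = 2)
#' nwEstimate(matrix(0.5, 1, 2), s, rowSums(s), h = c(0.3, 0.3))
#' @export
nwEstimate <- function(query, points, y, h, massFloor = 1e-3) {
  query <- as.matrix(query); points <- as.matrix(points)
  storage.mode(query) <- "double"; storage.mode(points) <- "double"
  stopifnot(nrow(points) >= 1, length(y) == nrow(points),
            ncol(query) == ncol(points), length(h) == ncol(points),
            all(h > 0))
  res <- nw_cpp(query, points, as.numeric(y), as.numeric(h))
  floor_ <- massFloor * expectedUniformMass(points, h)
  missing <- res$mass < floor_ | res$mass == 0
  est <- res$estimate
  est[missing] <- NA_real_
  list(estimate = est, mass = res$mass, missing = missing)
}

# NW estimates over a full rectangular (x2, x3) lattice, exploiting the
# separability of the product kernel: the dense query-by-sample weight
# matrix factorizes into two small one-dimensional kernel matrices and the
# sums become BLAS matrix products. Numerically equivalent to the generic
# path up to summation order. Samples are processed in blocks to bound
# memory at large n.
nwLatticeEstimate <- function(grid, ux2, ux3, pts, y, h, block = 20000L) {
  den <- matrix(0, length(ux2), length(ux3))
  num <- matrix(0, length(ux2), length(ux3))
  n <- nrow(pts)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(n, start + block - 1L)
    A <- gaussianKernel(outer(ux2, pts[idx, 1], "-") / h[1])
    B <- gaussianKernel(outer(ux3, pts[idx, 2], "-") / h[2])
    den <- den + A %*% t(B)
    num <- num + A %*% (t(B) * y[idx]) # rows of t(B) are samples
  }
  i <- cbind(match(grid$x2, ux2), match(grid$x3, ux3))
  list(estimate = num[i] / den[i], mass = den[i])
}

# Dispatch between the lattice fast path and the generic C++ loop, applying
# the weight-mass underflow floor either way.
nwGridEstimate <- function(grid, pts, y, h, dims, massFloor) {
  lattice <- identical(dims, c("x2", "x3"))
  if (lattice) {
    ux2 <- sort(unique(grid$x2)); ux3 <- sort(unique(grid$x3))
    lattice <- nrow(grid) == length(ux2) * length(ux3)
  }
  if (lattice) {
    res <- nwLatticeEstimate(grid, ux2, ux3, pts, as.numeric(y), h)
    floor_ <- massFloor * expectedUniformMass(pts, h)
    missing <- res$mass < floor_ | res$mass == 0
    est <- res$estimate
    est[missing] <- NA_real_
    list(estimate = est, mass = res$mass, missing = missing)
  } else {
    nwEstimate(recordPoints(grid, dims), pts, y, h, massFloor)
  }
}

# Extract the (points, g, f, m) sample set from a record data.frame for the
# given smoothing dimensions.
recordPoints <- function(rec, dims) {
  miss <- setdiff(dims, names(rec))
  if (length(miss))
    stop("records lack smoothing dimension(s): ", paste(miss, collapse = ", "))
  as.matrix(rec[, dims, drop = FALSE])
}

#' Smooth simulation records into a target surface
#'
#' Applies Nadaraya-Watson regression over the grid, by default in the two
#' free dimensions `(x2, x3)` (`x1` is budget-determined and collinear with
#' `x2`; passing `dims = c("x1", "x2", "x3")` expresses the full
#' three-dimensional estimator). Gain `g` and inbreeding `f` are smoothed
#' separately -- `f` with bandwidths scaled by `fScale` -- and the composite
#' surface is composed as `m_hat = g_hat - w * f_hat`
#' (`compose = "separate"`, the default, which is the only coherent reading
#' of response-specific bandwidths); `compose = "direct"` instead smooths
#' the `m` realizations with the `g` bandwidths.
#'
#' @param rec data.frame of simulation records with columns `x2`, `x3`
#'   (plus `x1` if used), `g`, `f` (and `m` for `compose = "direct"`).
#' @param grid data.frame of grid designs (as from [enumerateGrid()]).
#' @param bandwidths a [Bandwidths-class]; its `h` names select `dims` by
#'   default.
#' @param target a [TargetSpec-class] providing the inbreeding weight.
#' @param dims character vector of smoothing dimensions.
#' @param compose "separate" or "direct".
#' @param massFloor see [nwEstimate()].
#' @return a [KernelSurface-class].
#' @export
smoothSurface <- function(rec, grid, bandwidths = Bandwidths(),
                          target = TargetSpec(),
                          dims = names(hValues(bandwidths)),
                          compose = c("separate", "direct"),
                          massFloor = 1e-3) {
  compose <- match.arg(compose)
  stopifnot(is(bandwidths, "Bandwidths"), is(target, "TargetSpec"),
            nrow(grid) >= 1)
  pts <- recordPoints(rec, dims)
  hg <- hValues(bandwidths, "g")
  hf <- hValues(bandwidths, "f")
  g <- nwGridEstimate(grid, pts, rec$g, hg, dims, massFloor)
  f <- nwGridEstimate(grid, pts, rec$f, hf, dims, massFloor)
  w <- target@inbreedingWeight
  if (compose == "separate") {
    mHat <- g$estimate - w * f$estimate
    missing <- g$missing | f$missing
  } else {
    m <- rec$m
    if (is.null(m)) m <- rec$g - w * rec$f
    mm <- nwGridEstimate(grid, pts, m, hg, dims, massFloor)
    mHat <- mm$estimate
    missing <- mm$missing
  }
  mHat[missing] <- NA_real_
  new("KernelSurface", grid = as.data.frame(grid), gHat = g$estimate,
      fHat = f$estimate, mHat = mHat, massG = g$mass, massF = f$mass,
      missing = missing, bandwidths = bandwidths, method = "nw")
}

#' Piecewise-linear interpolation baseline surface
#'
#' The comparison baseline: duplicate sample locations in the `(x2, x3)`
#' plane are averaged, the unique locations are triangulated (Delaunay) and
#' `g`, `f` and `m` are interpolated barycentrically onto the grid. Grid
#' points outside the convex hull of the sample locations are flagged
#' missing. Interpolation is linear in the responses, so interpolating `m`
#' directly and composing `g - w * f` coincide.
#'
#' @inheritParams smoothSurface
#' @return a [KernelSurface-class] with `method = "linear"`.
#' @export
linearBaselineSurface <- function(rec, grid, target = TargetSpec()) {
  stopifnot(is(target, "TargetSpec"), nrow(grid) >= 1)
  w <- target@inbreedingWeight
  m <- rec$m
  if (is.null(m)) m <- rec$g - w * rec$f
  key <- paste(rec$x2, rec$x3)
  sums <- rowsum(cbind(g = as.numeric(rec$g), f = as.numeric(rec$f),
                       m = as.numeric(m), n = 1), group = key)
  if (nrow(sums) < 3) stop("degenerate geometry: need >= 3 distinct sample locations")
  first <- rec[!duplicated(key), c("x2", "x3")]
  first <- first[match(rownames(sums), paste(first$x2, first$x3)), ]
  z <- sums[, c("g", "f", "m")] / sums[, "n"]
  vals <- delaunay_interp_cpp(as.numeric(first$x2), as.numeric(first$x3), z,
                              as.numeric(grid$x2), as.numeric(grid$x3))
  missing <- is.na(vals[, 3])
  new("KernelSurface", grid = as.data.frame(grid), gHat = vals[, 1],
      fHat = vals[, 2], mHat = vals[, 3],
      massG = rep(NA_real_, nrow(grid)), massF = rep(NA_real_, nrow(grid)),
      missing = missing, bandwidths = Bandwidths(), method = "linear")
}

#' Cross-validation bandwidth selection
#'
#' Scores each candidate [Bandwidths-class] by squared prediction error of
#' the Nadaraya-Watson estimate for the chosen response: leave-one-out for
#' sample sizes up to `looThreshold`, 10-fold (with seeded, and therefore
#' deterministic, fold assignment) above it to bound cost. Returns the
#' candidate with the smallest error; ties keep the earlier candidate.
#'
#' @param rec data.frame of simulation records.
#' @param candidates list of [Bandwidths-class] candidates.
#' @param response which response to cross-validate ("g", "f" or "m").
#' @param dims smoothing dimensions.
#' @param looThreshold sample size above which 10-fold CV replaces
#'   leave-one-out.
#' @param foldSeed seed for the fold assignment.
#' @return the selected [Bandwidths-class], with a `"cvError"` attribute
#'   holding the per-candidate errors.
#' @export
cvBandwidth <- function(rec, candidates, response = c("g", "f", "m"),
                        dims = NULL, looThreshold = 500L, foldSeed = 1L) {
  response <- match.arg(response)
  stopifnot(length(candidates) >= 1, nrow(rec) >= 10)
  if (is.null(dims)) dims <- names(hValues(candidates[[1]]))
  pts <- recordPoints(rec, dims)
  y <- switch(response, g = rec$g, f = rec$f,
              m = if (is.null(rec$m)) rec$g - 50 * rec$f else rec$m)
  n <- nrow(pts)
  folds <- NULL
  if (n > looThreshold)
    folds <- withSeed(foldSeed, sample(rep_len(1:10, n)))
  errs <- vapply(candidates, function(bw) {
    h <- hValues(bw, response)
    if (length(h) != length(dims))
      stop("candidate bandwidth length does not match dims")
    if (is.null(folds)) {
      pred <- nw_loo_cpp(pts, as.numeric(y), as.numeric(h))
    } else {
      pred <- numeric(n)
      for (k in 1:10) {
        hold <- folds == k
        fit <- nw_cpp(pts[hold, , drop = FALSE], pts[!hold, , drop = FALSE],
                      as.numeric(y[!hold]), as.numeric(h))
        pred[hold] <- fit$estimate
      }
    }
    bad <- !is.finite(pred)
    pred[bad] <- mean(y) # a fold with no kernel mass predicts the global mean
    sum((y - pred)^2)
  }, numeric(1))
  best <- which.min(errs)
  out <- candidates[[best]]
  attr(out, "cvError") <- errs
  out
}
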