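#' @import methods
#' @importFrom stats rnorm runif qnorm dnorm sd var
#' @importFrom utils head tail
#' @useDynLib breedoptim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Annual budget and housing costs of a progeny-testing scheme
#'
#' The feasible region of designs is bounded by a fixed annual budget:
#' a candidate design housing `x1` test daughters and `x2` test bulls is
#' affordable when `costPerCow * x1 + costPerBull * x2 <= totalBudget`.
#' The number of selected sires (`x3`) does not enter the constraint because
#' sires are drawn from already-housed test bulls.
#'
#' @slot totalBudget annual budget, currency units per year.
#' @slot costPerCow housing cost per cow and year.
#' @slot costPerBull housing cost per bull and year.
#'
#' @examples
#' b <- BudgetModel()
#' totalBudget(b)
#' @export
setClass("BudgetModel",
  representation(totalBudget = "numeric", costPerCow = "numeric",
                 costPerBull = "numeric"),
  prototype(totalBudget = 1e7, costPerCow = 4000, costPerBull = 3000))

setValidity("BudgetModel", function(object) {
  v <- c(object@totalBudget, object@costPerCow, object@costPerBull)
  if (length(v) != 3L || any(!is.finite(v)) || any(v <= 0))
    return("totalBudget, costPerCow and costPerBull must be single positive numbers")
  TRUE
})

#' @rdname BudgetModel-class
#' @param totalBudget,costPerCow,costPerBull see slots.
#' @export
BudgetModel <- function(totalBudget = 1e7, costPerCow = 4000, costPerBull = 3000) {
  new("BudgetModel", totalBudget = totalBudget, costPerCow = costPerCow,
      costPerBull = costPerBull)
}

#' Bounds of the decision variables
#'
#' Inclusive integer ranges for the number of test bulls (`x2`) and the
#' number of selected sires (`x3`). The number of test daughters (`x1`) is
#' not bounded directly; it is determined from the residual budget (see
#' [allocateDaughters()]).
#'
#' @slot x2Min,x2Max inclusive bounds on the number of test bulls.
#' @slot x3Min,x3Max inclusive bounds on the number of selected sires.
#' @export
setClass("ParameterBounds",
  representation(x2Min = "integer", x2Max = "integer",
                 x3Min = "integer", x3Max = "integer"),
  prototype(x2Min = 100L, x2Max = 700L, x3Min = 3L, x3Max = 30L))

setValidity("ParameterBounds", function(object) {
  v <- c(object@x2Min, object@x2Max, object@x3Min, object@x3Max)
  if (length(v) != 4L || any(is.na(v)) || any(v <= 0L))
    return("all bounds must be single positive integers")
  if (object@x2Min > object@x2Max) return("x2Min must be <= x2Max")
  if (object@x3Min > object@x3Max) return("x3Min must be <= x3Max")
  TRUE
})

#' @rdname ParameterBounds-class
#' @param x2Min,x2Max,x3Min,x3Max inclusive integer bounds.
#' @export
ParameterBounds <- function(x2Min = 100L, x2Max = 700L, x3Min = 3L, x3Max = 30L) {
  new("ParameterBounds", x2Min = as.integer(x2Min), x2Max = as.integer(x2Max),
      x3Min = as.integer(x3Min), x3Max = as.integer(x3Max))
}

#' Composite breeding target specification
#'
#' The composite target trades genetic gain against inbreeding:
#' `m = sum_t w_t g_t - inbreedingWeight * f`, where `g_t` is the genetic
#' gain after year `t` and `f` the mean pairwise kinship of the final
#' newborn cohort. With empty `horizonWeights` (the default) all gain weight
#' is on the final year, giving `m = g - w * f`; the default weight is 50,
#' chosen to put the two goals on comparable scales.
#'
#' @slot inbreedingWeight non-negative scalar penalty on `f`.
#' @slot horizonWeights named numeric vector of per-year gain weights
#'   (names are years); empty means all weight on the final year.
#' @export
setClass("TargetSpec",
  representation(inbreedingWeight = "numeric", horizonWeights = "numeric"),
  prototype(inbreedingWeight = 50, horizonWeights = numeric(0)))

setValidity("TargetSpec", function(object) {
  if (length(object@inbreedingWeight) != 1L || !is.finite(object@inbreedingWeight) ||
      object@inbreedingWeight < 0)
    return("inbreedingWeight must be a single non-negative number")
  hw <- object@horizonWeights
  if (length(hw)) {
    if (is.null(names(hw)) || any(is.na(suppressWarnings(as.integer(names(hw))))))
      return("horizonWeights must be named by (integer) years")
    if (any(hw < 0) || all(hw == 0))
      return("horizonWeights must be non-negative with at least one positive entry")
  }
  TRUE
})

#' @rdname TargetSpec-class
#' @param inbreedingWeight,horizonWeights see slots.
#' @export
TargetSpec <- function(inbreedingWeight = 50, horizonWeights = numeric(0)) {
  new("TargetSpec", inbreedingWeight = inbreedingWeight,
      horizonWeights = horizonWeights)
}

#' Configuration of the progeny-testing scheme simulator
#'
#' Fixed parameters of the simulated dairy scheme: the trait follows the
#' infinitesimal model with additive variance `additiveVariance` and
#' heritability `heritability`; the scheme runs for `years` discrete yearly
#' cycles. Founder herd sizes default (`NA`) to the design under evaluation:
#' `founderCows = x1`, `founderBulls = x2`. Each year a fraction
#' `damReplacement` of the cow herd is replaced by newborn heifers; cows
#' breed from age 2 for up to 4 years, and bulls are usable as sires the
#' year after their progeny test.
#'
#' @slot years number of simulated breeding years.
#' @slot heritability narrow-sense heritability in (0, 1].
#' @slot additiveVariance additive genetic variance (gain is reported in
#'   units of the initial genetic standard deviation when this is 1).
#' @slot founderCows,founderBulls founder counts, `NA` = taken from the design.
#' @slot damReplacement fraction of the cow herd replaced per year.
#' @export
setClass("SchemeConfig",
  representation(years = "integer", heritability = "numeric",
                 additiveVariance = "numeric", founderCows = "integer",
                 founderBulls = "integer", damReplacement = "numeric"),
  prototype(years = 15L, heritability = 0.3, additiveVariance = 1.0,
            founderCows = NA_integer_, founderBulls = NA_integer_,
            damReplacement = 0.25))

setValidity("SchemeConfig", function(object) {
  if (object@years < 1L) return("years must be >= 1")
  if (!is.finite(object@heritability) || object@heritability <= 0 ||
      object@heritability > 1)
    return("heritability must be in (0, 1]")
  if (!is.finite(object@additiveVariance) || object@additiveVariance < 0)
    return("additiveVariance must be non-negative")
  if (!is.na(object@founderCows) && object@founderCows <= 0L)
    return("founderCows must be positive")
  if (!is.na(object@founderBulls) && object@founderBulls <= 0L)
    return("founderBulls must be positive")
  if (object@damReplacement <= 0 || object@damReplacement > 1)
    return("damReplacement must be in (0, 1]")
  TRUE
})

#' @rdname SchemeConfig-class
#' @param years,heritability,additiveVariance,founderCows,founderBulls,damReplacement
#'   see slots.
#' @export
SchemeConfig <- function(years = 15L, heritability = 0.3, additiveVariance = 1.0,
                         founderCows = NA, founderBulls = NA,
                         damReplacement = 0.25) {
  new("SchemeConfig", years = as.integer(years), heritability = heritability,
      additiveVariance = additiveVariance, founderCows = as.integer(founderCows),
      founderBulls = as.integer(founderBulls), damReplacement = damReplacement)
}

#' Per-dimension kernel bandwidths
#'
#' Bandwidths of the product Gaussian kernel, one per smoothing dimension.
#' The inbreeding response `f` changes much more sharply at high selection
#' intensity (small `x3`) than the gain `g`, so its bandwidths are scaled by
#' `fScale` (default 1/3) relative to `h`.
#'
#' @slot h named positive numeric vector of bandwidths per dimension
#'   (default `c(x2 = 30, x3 = 1)`, the first-iteration bandwidth for `g`).
#' @slot fScale multiplier applied to `h` when smoothing `f` (default 1/3).
#' @export
setClass("Bandwidths",
  representation(h = "numeric", fScale = "numeric"),
  prototype(h = c(x2 = 30, x3 = 1), fScale = 1 / 3))

setValidity("Bandwidths", function(object) {
  if (!length(object@h) || any(!is.finite(object@h)) || any(object@h <= 0))
    return("h must be a vector of positive bandwidths")
  if (is.null(names(object@h)) || any(!nzchar(names(object@h))))
    return("h must be named by smoothing dimension (e.g. x2, x3)")
  if (length(object@fScale) != 1L || !is.finite(object@fScale) || object@fScale <= 0)
    return("fScale must be a single positive number")
  TRUE
})

#' @rdname Bandwidths-class
#' @param h,fScale see slots.
#' @export
Bandwidths <- function(h = c(x2 = 30, x3 = 1), fScale = 1 / 3) {
  new("Bandwidths", h = h, fScale = fScale)
}

#' Smoothed target surface over a grid of designs
#'
#' Holds Nadaraya-Watson (or baseline) estimates of genetic gain, inbreeding
#' and the composite target over a grid of candidate designs, together with
#' the kernel weight mass behind each estimate and a missingness flag for
#' grid points where the weight mass underflows (or, for the linear
#' baseline, points outside the convex hull of the samples).
#'
#' @slot grid data.frame with columns x1, x2, x3.
#' @slot gHat,fHat,mHat numeric estimates per grid point (NA where missing).
#' @slot massG,massF kernel weight mass per grid point (NA for the baseline).
#' @slot missing logical flag per grid point.
#' @slot bandwidths the [Bandwidths-class] used (for kernel surfaces).
#' @slot method "nw" or "linear".
#' @export
setClass("KernelSurface",
  representation(grid = "data.frame", gHat = "numeric", fHat = "numeric",
                 mHat = "numeric", massG = "numeric", massF = "numeric",
                 missing = "logical", bandwidths = "Bandwidths",
                 method = "character"))

setValidity("KernelSurface", function(object) {
  n <- nrow(object@grid)
  if (!all(c("x2", "x3") %in% names(object@grid)))
    return("grid must have columns x2 and x3")
  lens <- c(length(object@gHat), length(object@fHat), length(object@mHat),
            length(object@missing))
  if (any(lens != n)) return("estimate vectors must match the grid length")
  if (any(!is.finite(object@mHat) & !object@missing))
    return("estimates must be finite wherever not flagged missing")
  TRUE
})

#' Rectangular search box in the (x2, x3) plane
#'
#' @slot x2Range,x3Range inclusive integer intervals `c(lo, hi)`.
#' @export
setClass("SearchBox",
  representation(x2Range = "integer", x3Range = "integer"),
  prototype(x2Range = c(100L, 700L), x3Range = c(3L, 30L)))

setValidity("SearchBox", function(object) {
  for (r in list(object@x2Range, object@x3Range)) {
    if (length(r) != 2L || any(is.na(r)) || r[1] > r[2])
      return("ranges must be c(lo, hi) with lo <= hi")
  }
  TRUE
})

#' @rdname SearchBox-class
#' @param x2Range,x3Range inclusive integer intervals `c(lo, hi)`.
#' @export
SearchBox <- function(x2Range = c(100L, 700L), x3Range = c(3L, 30L)) {
  new("SearchBox", x2Range = as.integer(x2Range), x3Range = as.integer(x3Range))
}

#' Synthetic noisy objective with a known optimum
#'
#' An analytic stand-in for the breeding simulator used to test the
#' smoothing/optimization pipeline at desk scale: deterministic surfaces
#' `gFun(x2, x3)` and `fFun(x2, x3)` observed with Gaussian noise. The true
#' argmax of the implied composite target is stored so recovery can be
#' scored exactly.
#'
#' @slot gFun,fFun vectorized functions of (x2, x3).
#' @slot noiseSdG,noiseSdF realization noise standard deviations.
#' @slot argmax numeric `c(x2, x3)` location of the true optimum of m.
#' @slot label short description.
#' @export
setClass("SyntheticObjective",
  representation(gFun = "function", fFun = "function", noiseSdG = "numeric",
                 noiseSdF = "numeric", argmax = "numeric", label = "character"))

setValidity("SyntheticObjective", function(object) {
  if (object@noiseSdG < 0 || object@noiseSdF < 0)
    return("noise standard deviations must be >= 0")
  if (length(object@argmax) != 2L || any(!is.finite(object@argmax)))
    return("argmax must be a finite c(x2, x3)")
  TRUE
})

#' One stochastic realization of the breeding scheme
#'
#' @slot g genetic gain: mean true breeding value of the final-year newborn
#'   cohort minus the founder mean, in initial genetic SD units.
#' @slot f inbreeding level: mean pairwise kinship of the final newborn cohort.
#' @slot m composite target value under the [TargetSpec-class] used.
#' @slot perYearG,perYearF per-year trajectories (length = years).
#' @slot sirePathG per-year mean true breeding value of the selected sires.
#' @slot pedigree data.frame of animal records (id, sire_id, dam_id, sex,
#'   birth_year, true_bv, ebv, inbreeding_coeff).
#' @slot params the evaluated design `c(x1, x2, x3)`.
#' @export
setClass("SimOutcome",
  representation(g = "numeric", f = "numeric", m = "numeric",
                 perYearG = "numeric", perYearF = "numeric",
                 sirePathG = "numeric", pedigree = "data.frame",
                 params = "numeric"))

setValidity("SimOutcome", function(object) {
  if (object@f < 0 || object@f > 1) return("f must lie in [0, 1]")
  if (length(object@perYearG) != length(object@perYearF))
    return("trajectories must have equal length")
  TRUE
})

#' Report of an iterative optimization run
#'
#' @slot iterations list of per-iteration states, each a list with elements
#'   `index`, `box`, `bandwidths`, `nNew`, `optimum` (list of `par`, `value`),
#'   and `maxima` (data.frame of local maxima).
#' @slot optimum final optimum, `list(par, value)`.
#' @slot converged logical convergence flag.
#' @slot reason human-readable stopping reason.
#' @slot records all accumulated simulation records.
#' @export
setClass("OptimizationReport",
  representation(iterations = "list", optimum = "list", converged = "logical",
                 reason = "character", records = "data.frame"))

setValidity("OptimizationReport", function(object) {
  if (length(object@iterations)) {
    last <- object@iterations[[length(object@iterations)]]
    if (!identical(last$optimum$par, object@optimum$par))
      return("final optimum must equal the last iteration's optimum")
  }
  TRUE
})

#' Result of the bootstrap comparison of smoothing methods
#'
#' @slot summary data.frame with one row per method: mean target value of
#'   the suggested optima (scored on the full-set reference surface) and
#'   mean Euclidean distance of the suggested optima from the full-set optimum.
#' @slot replicates replicate-level values (one row per draw and method).
#' @slot nFailed number of draws on which a smoother failed (excluded).
#' @slot reference list with the reference surface and its optimum.
#' @export
setClass("ComparisonResult",
  representation(summary = "data.frame", replicates = "data.frame",
                 nFailed = "integer", reference = "list"))

setValidity("ComparisonResult", function(object) {
  for (meth in object@summary$method) {
    rep <- object@replicates[object@replicates$method == meth, ]
    s <- object@summary[object@summary$method == meth, ]
    if (nrow(rep) && abs(mean(rep$distance) - s$meanDistance) > 1e-8)
      return("summary means must equal the average of replicate-level values")
  }
  TRUE
})

#' Result of the optimum-location stability analysis
#'
#' @slot optima data.frame of estimated optima (size, rep, x2, x3, value).
#' @slot fractions data.frame per sample size: fraction of optima inside
#'   the reference region.
#' @slot density list of kernel density summaries of optimum locations,
#'   one per sample size (grid + density values).
#' @slot region the reference [SearchBox-class].
#' @export
setClass("StabilityResult",
  representation(optima = "data.frame", fractions = "data.frame",
                 density = "list", region = "SearchBox"))

setValidity("StabilityResult", function(object) {
  fr <- object@fractions$fraction
  if (length(fr) && (any(fr < 0) || any(fr > 1)))
    return("fractions must lie in [0, 1]")
  TRUE
})

#' Validated run configuration
#'
#' Aggregates the configuration of every pipeline stage. Built by
#' [loadConfig()] from a YAML or JSON file with documented defaults filled
#' in; unknown keys are rejected.
#'
#' @slot budget [BudgetModel-class].
#' @slot bounds [ParameterBounds-class].
#' @slot target [TargetSpec-class].
#' @slot scheme [SchemeConfig-class].
#' @slot smoothing list: `h0` ([Bandwidths-class]), `cv` flag.
#' @slot optimizer list: `nSims`, `padding`, `factor`, `tolerance`,
#'   `maxIterations`, `minSeparation`, `nMaximaKeep`, `gridStep`.
#' @slot evaluation list: `nBoot`, `subsampleSize`, `sizes`, `nRep`.
#' @slot seed global seed.
#' @slot outDir output directory.
#' @export
setClass("RunConfig",
  representation(budget = "BudgetModel", bounds = "ParameterBounds",
                 target = "TargetSpec", scheme = "SchemeConfig",
                 smoothing = "list", optimizer = "list", evaluation = "list",
                 seed = "numeric", outDir = "character"))
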