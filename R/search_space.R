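# Search space of progeny-testing designs: budget allocation, feasibility,
# uniform sampling and grid enumeration.

#' Allocate test daughters from the residual budget
#'
#' Given the number of test bulls `x2`, returns the largest number of test
#' daughters `x1` the annual budget can still house:
#' `x1 = floor((totalBudget - costPerBull * x2) / costPerCow)`.
#' With the default budget model (10M budget, 4,000 per cow, 3,000 per bull)
#' this reproduces e.g. `x2 = 100 -> x1 = 2425` and `x2 = 163 -> x1 = 2377`.
#'
#' @param x2 number of test bulls (vectorized, non-negative integers).
#' @param budget a [BudgetModel-class].
#' @return integer vector of test-daughter counts.
#' @examples
#' allocateDaughters(c(100, 163, 184))
#' @export
allocateDaughters <- function(x2, budget = BudgetModel()) {
  stopifnot(is(budget, "BudgetModel"))
  if (any(x2 < 0)) stop("x2 must be non-negative")
  residual <- totalBudget(budget) - costPerBull(budget) * x2
  bad <- residual < 0
  if (any(bad))
    stop(sprintf("bull housing alone exceeds the budget for x2 = %s",
                 paste(x2[bad], collapse = ", ")))
  as.integer(floor(residual / costPerCow(budget)))
}

#' Feasibility of a candidate design
#'
#' A design `(x1, x2, x3)` is feasible when all counts are non-negative
#' integers, `x3 <= x2`, `x2` and `x3` lie inside their bounds, and the
#' housing cost `costPerCow * x1 + costPerBull * x2` does not exceed the
#' annual budget. Violations return `FALSE` rather than an error.
#'
#' @param x1,x2,x3 design counts (vectorized).
#' @param bounds a [ParameterBounds-class].
#' @param budget a [BudgetModel-class].
#' @return logical vector.
#' @examples
#' isFeasible(2425, 100, 3)
#' isFeasible(2500, 100, 3)   # over budget
#' @export
isFeasible <- function(x1, x2, x3, bounds = ParameterBounds(),
                       budget = BudgetModel()) {
  stopifnot(is(bounds, "ParameterBounds"), is(budget, "BudgetModel"))
  ok <- x1 >= 0 & x2 >= 0 & x3 >= 0 &
    x1 == floor(x1) & x2 == floor(x2) & x3 == floor(x3) &
    x3 <= x2 &
    x2 >= x2Range(bounds)[1] & x2 <= x2Range(bounds)[2] &
    x3 >= x3Range(bounds)[1] & x3 <= x3Range(bounds)[2] &
    costPerCow(budget) * x1 + costPerBull(budget) * x2 <= totalBudget(budget)
  ok & !is.na(ok)
}

#' Sample candidate designs uniformly over the feasible region
#'
#' Draws `x2` and `x3` from discrete uniform distributions over their
#' bounds, resampling pairs until `x3 <= x2` (always true for the default
#' bounds), and allocates `x1` from the residual budget via
#' [allocateDaughters()]. Infeasible pairs are rejected, not clipped, so the
#' draw stays uniform on the feasible region.
#'
#' @param n number of designs to sample.
#' @param bounds a [ParameterBounds-class].
#' @param budget a [BudgetModel-class].
#' @param seed optional RNG seed for reproducibility (the caller's RNG state
#'   is left untouched when given).
#' @return data.frame with columns x1, x2, x3.
#' @examples
#' head(sampleParametrizations(5, seed = 1))
#' @export
sampleParametrizations <- function(n, bounds = ParameterBounds(),
                                   budget = BudgetModel(), seed = NULL) {
  stopifnot(n >= 1, is(bounds, "ParameterBounds"), is(budget, "BudgetModel"))
  r2 <- x2Range(bounds); r3 <- x3Range(bounds)
  if (costPerBull(budget) * r2[1] > totalBudget(budget))
    stop("empty feasible region: bull housing for x2Min alone exceeds the budget")
  if (r3[1] > r2[2])
    stop("empty feasible region: x3Min exceeds x2Max")
  withSeed(seed, {
    x2 <- integer(0); x3 <- integer(0)
    while (length(x2) < n) {
      k <- n - length(x2)
      c2 <- r2[1] + sample.int(r2[2] - r2[1] + 1L, k, replace = TRUE) - 1L
      c3 <- r3[1] + sample.int(r3[2] - r3[1] + 1L, k, replace = TRUE) - 1L
      keep <- c3 <= c2 & costPerBull(budget) * c2 <= totalBudget(budget)
      x2 <- c(x2, c2[keep]); x3 <- c(x3, c3[keep])
    }
    data.frame(x1 = allocateDaughters(x2, budget), x2 = x2, x3 = x3)
  })
}

#' Enumerate the full integer design grid
#'
#' All integer `(x2, x3)` pairs inside the inclusive bounds with
#' `x3 <= x2`, each with its budget-allocated `x1`, in lexicographic
#' `(x2, x3)` order. Optional step sizes give coarser evaluation grids.
#'
#' @param bounds a [ParameterBounds-class] or [SearchBox-class].
#' @param budget a [BudgetModel-class].
#' @param stepX2,stepX3 positive integer grid steps (default 1).
#' @return data.frame with columns x1, x2, x3.
#' @examples
#' nrow(enumerateGrid())  # 601 * 28 cells under default bounds
#' @export
enumerateGrid <- function(bounds = ParameterBounds(), budget = BudgetModel(),
                          stepX2 = 1L, stepX3 = 1L) {
  stopifnot(is(budget, "BudgetModel"), stepX2 >= 1, stepX3 >= 1)
  r2 <- x2Range(bounds); r3 <- x3Range(bounds)
  g <- expand.grid(x3 = seq(r3[1], r3[2], by = as.integer(stepX3)),
                   x2 = seq(r2[1], r2[2], by = as.integer(stepX2)))
  g <- g[g$x3 <= g$x2, c("x2", "x3")]
  g <- g[order(g$x2, g$x3), ]
  rownames(g) <- NULL
  data.frame(x1 = allocateDaughters(g$x2, budget), x2 = as.integer(g$x2),
             x3 = as.integer(g$x3))
}

#' Search-space reduction factor between two boxes
#'
#' Bookkeeping for the iterative narrowing: the ratio of the grid cell
#' counts of two search boxes. `counting = "span"` multiplies the per
#' dimension spans `max - min` (the convention behind the reported 27x600
#' vs 9x130 grids, whose ratio rounds to 14); `counting = "inclusive"`
#' multiplies inclusive integer counts `max - min + 1`.
#'
#' @param boxA,boxB [SearchBox-class] objects (A before narrowing).
#' @param counting "span" or "inclusive".
#' @return ratio of cell counts (A / B).
#' @examples
#' reductionFactor(SearchBox(c(100, 700), c(3, 30)),
#'                 SearchBox(c(120, 250), c(13, 22)))
#' @export
reductionFactor <- function(boxA, boxB, counting = c("span", "inclusive")) {
  counting <- match.arg(counting)
  cells <- function(b) {
    s2 <- diff(x2Range(b)); s3 <- diff(x3Range(b))
    if (counting == "inclusive") (s2 + 1) * (s3 + 1) else s2 * s3
  }
  a <- cells(boxA); b <- cells(boxB)
  if (b == 0) stop("box B has zero cells under span counting")
  a / b
}

# Coerce a SearchBox to ParameterBounds (used for in-box sampling).
boxToBounds <- function(box) {
  ParameterBounds(x2Range(box)[1], x2Range(box)[2],
                  x3Range(box)[1], x3Range(box)[2])
}
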