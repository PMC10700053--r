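---
title: "Optimizing breeding program designs by smoothing stochastic simulations"
author: "breedoptim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing breeding program designs by smoothing stochastic simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedoptim)
```

## The optimization problem

A progeny-testing dairy program is described by three decision variables:
the number of test daughters `x1`, the number of test bulls `x2`, and the
number of selected sires `x3`. Housing costs (default 4,000 per cow-year and
3,000 per bull-year) must fit a fixed annual budget (default 10 M), which
yields the constraint

\[
4{,}000\,x_1 + 3{,}000\,x_2 - 10{,}000{,}000 \le 0,
\qquad 100 \le x_2 \le 700,\qquad 3 \le x_3 \le 30 .
\]

Selected sires are drawn from the already-housed test bulls, so `x3` does not
appear in the cost constraint. Because every cow-place not used for testing
bulls should be testing daughters, `x1` is treated as fully determined by
budget exhaustion, `x1 = floor((B - 3000 x2) / 4000)` ([allocateDaughters()]);
the two free dimensions are `(x2, x3)`.

The breeding goal is a composite of genetic gain `g` (mean true breeding
value of the newborn cohort after 15 years, in units of the initial genetic
standard deviation) and the inbreeding level `f` (mean pairwise kinship of
that cohort):

\[
m(x_1,x_2,x_3) \;=\; g(x_1,x_2,x_3) \;-\; w\, f(x_1,x_2,x_3),
\qquad w = 50 \text{ by default},
\]

where `w` puts the two goals on roughly comparable scales. `TargetSpec`
also accepts per-year horizon weights so that gains at years 1, 2, 3, 5 and
10 can enter the target alongside the final year.

`m` can only be *realized* by stochastic simulation: each evaluation of a
design returns `m` plus substantial Monte-Carlo noise. The package's core is
therefore (i) a stochastic scheme simulator, (ii) Nadaraya–Watson kernel
regression turning noisy realizations into an estimable surface
\(\hat m(x_2, x_3)\), and (iii) an iterative optimizer that narrows the
search box and sharpens the bandwidth until the estimated optimum is stable.

## The scheme simulator

`simulateScheme()` runs discrete yearly cycles of a deliberately simple
progeny-testing scheme under the infinitesimal model:

* **Trait model.** Offspring true breeding value = mid-parent +
  Mendelian-sampling deviation with variance
  \(\sigma_a^2\,(1 - (F_s + F_d)/2)/2\). Defaults: \(\sigma_a^2 = 1\),
  heritability 0.3.
* **Information.** Each test bull is rated by `floor(x1 / x2)` daughters;
  daughter phenotypes are integrated out analytically into an EBV with the
  classical half-sib accuracy
  \(r = \sqrt{\,n h^2/4 \,/\, (1 + (n-1) h^2/4)\,}\), so test daughters do
  not have to be simulated individually.
* **Selection.** Truncation on EBV: the `x3` best of the `x2` tested bulls
  become the sires of the next cohort (ties broken by lower animal id, for
  determinism). Dams are drawn at random among cows of breeding age (2–5);
  the decision variables only control the sire path.
* **Turnover.** A fraction (default 0.25) of the cow herd is replaced by
  newborn heifers each year; bulls sire for a single year, the year after
  testing.
* **Kinship.** Coancestry is propagated exactly by the tabular method on a
  rolling matrix of every animal that can still become a parent, so `f` is
  deterministic given the pedigree. `pedigreeKinship()` recomputes it
  independently from the full pedigree; a test asserts the two agree to
  machine precision.

This scheme is the package's own re-specification of a classical dairy
progeny-testing program: it is intentionally minimal (no genomic data, no
dam-path selection, no overlapping sire usage) and its absolute `g`/`f`
levels should not be compared against any particular real program. What the
simulator is *for* is producing realistically noisy, budget-constrained
realizations whose response to the decision variables has the right
structure: fewer sires → more selection intensity → more gain and more
kinship; more daughters per bull → higher accuracy → more gain. Tests check
exactly these monotonicities (paired seeds, sign tests) and the
one-generation breeder's-equation prediction \(i\,r\,\sigma_a\) against a
Monte-Carlo order-statistic oracle.

Each replicate runs on its own RNG stream derived from
`deriveSeed(globalSeed, replicate)`, so record batches are reproducible
independent of execution order.

## Kernel regression of the target surface

Given records \((x_{i}, y_i)\), the Nadaraya–Watson estimator is the locally
weighted average

\[
\hat m(x) = \frac{\sum_i y_i\, K\!\big(\tfrac{x - x_i}{h}\big)}
                 {\sum_i K\!\big(\tfrac{x - x_i}{h}\big)},
\qquad
K(u_1,\dots,u_d) = \prod_d \tfrac{1}{\sqrt{2\pi}} e^{-u_d^2/2},
\]

a product Gaussian kernel with one bandwidth per dimension. Defaults follow
the halving schedule `(h_x2, h_x3) = (30, 1) → (15, 0.5) → (7.5, 0.25)`
across iterations (`scheduleBandwidth()`). Because `f` changes sharply where
selection intensity is extreme (small `x3`), its bandwidths are the `g`
bandwidths divided by 3 in every iteration. Smoothing with response-specific
bandwidths is only coherent if the composite is assembled *after* smoothing,
so `smoothSurface()` composes \(\hat m = \hat g - w \hat f\) by default;
direct smoothing of `m` realizations is available as an option
(`compose = "direct"`).

Numerical choices worth knowing:

* **Smoothing dimensions.** `x1` is collinear with `x2` under budget
  exhaustion, so smoothing operates in `(x2, x3)` by default; the estimator
  accepts any dimension count, so the full 3-D form is expressible.
* **Underflow floor.** A grid point whose total kernel mass falls below
  `1e-3 ×` the mass expected under uniformly spread samples is flagged
  *missing* instead of extrapolated — far outside the sampled box the
  weighted average is dominated by a few distant records and is not a
  meaningful estimate. Zero mass is always missing.
* **Separable fast path.** On a full `(x2, x3)` lattice the weight matrix
  factorizes into two one-dimensional kernel matrices and the sums become
  BLAS products; a test pins this path to the generic C++ loop at 1e-12.
* **Bandwidth selection.** `cvBandwidth()` scores candidate bandwidths by
  leave-one-out squared prediction error (10-fold with a seeded fold split
  above 500 records, to bound cost). In practice the conservative default
  `(30, 1)` is a sensible first-iteration choice — early iterations need to
  find promising regions, not unbiased estimates.

The comparison baseline, `linearBaselineSurface()`, interpolates the
records piecewise-linearly: duplicate locations are averaged, the unique
locations Delaunay-triangulated (Bowyer–Watson), and grid points outside
the convex hull flagged missing. Sample coordinates are deterministically
joggled by ~1e-9 of the coordinate range before triangulating: integer
lattice data are full of exactly collinear/cocircular configurations, and
the joggle (the same idea as qhull's "joggle" option) resolves them at the
cost of an interpolation error of order 1e-6, absorbed by a matching
barycentric tolerance at the hull.

## The iterative optimizer

`runPipeline()` repeats: sample designs uniformly in the current box →
evaluate the stochastic objective → smooth `g` and `f` over the in-box grid
using **all** records accumulated so far → compose \(\hat m\) → brute-force
argmax (`bruteForceArgmax()`, ties lexicographic) and 8-neighborhood local
maxima (`findLocalMaxima()`) → narrow the box around the top maxima →
halve the bandwidth. It stops when the argmax moves by at most one grid
step per dimension between consecutive iterations, or after the configured
number of iterations. Design choices:

* **Box narrowing.** The smallest box containing the kept maxima is padded
  by half its own span per side (configurable), rounded outward and clipped
  to the global bounds. Additionally the box never shrinks below ±2 current
  bandwidths around the maxima-box center: a kernel argmax cannot be
  localized more finely than its smoothing window, and without this floor a
  single sharp maximum would collapse the box to one point.
* **Record reuse.** Records outside the new box still carry kernel weight
  near its boundary; discarding them causes visible edge bias, so they are
  retained in all later smoothing.
* **Simulation schedule.** The default `nSims = c(2000, 1500, 500)` mirrors
  a heavy exploratory first iteration followed by cheaper refinements;
  roughly a third of the total effort in iteration one is a sensible rule
  of thumb.

## The synthetic objective and what the tests show

Because the simulator itself is expensive and its exact optimum unknown,
the pipeline's end-to-end guarantees are established on
`quadraticObjective()`: a concave paraboloid
\(m^*(x_2, x_3) = 10 - a(x_2-400)^2 - b(x_3-15)^2\) observed through
`g = m* + w f + noise` (sd 1) and a flat `f ≡ 0.02` (sd 0.004), with the
argmax at (400, 15) by construction. The curvature defaults
`a = 0.005, b = 0.5` were fixed by a power argument before any test was
run: one `x3` grid step near the optimum moves the objective by half a
realization SD, and `x2` is ~16× flatter per squared unit, mirroring the
~20-fold scale difference between the two variables. This makes the optimum
identifiable at four-figure simulation budgets while single realizations
remain noise-dominated — a test surface whose optimum could not be
identified at the budgets used would test nothing.

With this fixture the suite verifies, at desk scale:

* the 3-iteration pipeline (2,000/1,500/500 evaluations) lands within one
  final-iteration bandwidth of the true argmax in ≥90 % of seeds;
* under bootstrap resampling (draws of 2,500 from 5,000 records), kernel
  regression suggests optima closer to the full-set optimum than linear
  interpolation in ≥80 % of repetitions;
* the fraction of single-shot optima falling in a fixed region around the
  true argmax is non-decreasing in the number of simulations
  (250 → 1,000 → 4,000, 50 repetitions each).

What passing these tests does *not* show: that the default bandwidths are
optimal for any particular real breeding program, that the quadratic shape
resembles a real target surface globally (real surfaces are flatter near
their optima and multi-modal), or that the simulator's absolute gain and
kinship levels are calibrated to field data. The synthetic surface has
homoscedastic noise; real simulation noise grows at high selection
intensity — the motivation for the narrower `f` bandwidths — and only the
direction of that effect, not its magnitude, is exercised here.

Problem sizes in the tests (record counts in the low thousands, 15-year
schemes with a 1–2 M budget, 30–50 repetitions) are the package's choice of
desk-scale defaults; all of them are plain arguments, and production runs
simply pass larger values.

## Limitations

* The simulator is a minimal single-trait scheme: no genomic selection, no
  optimum-contribution selection, no economic modeling, no overlapping sire
  generations.
* Kernel regression needs exponentially more samples as dimensions are
  added; with many decision variables a sequential strategy (or coupling
  the smoother with an external optimizer via the exported surfaces) is the
  realistic route. Only brute-force and grid-local-maxima search are
  implemented here; `writeSurface()` exports \(\hat m\) for any external
  optimizer.
* Gaussian kernels are uncorrected at the search-space boundary; corner
  estimates lean on one-sided data and carry extra bias, which the
  weight-mass flag only partially mitigates.
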