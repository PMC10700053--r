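# breedoptim

Numerical optimization of breeding-program design when the objective can
only be observed through stochastic simulation.

Designing a progeny-testing program means splitting a fixed annual budget
between test daughters (`x1`), test bulls (`x2`) and deciding how many
sires to select (`x3`). Every candidate design can be *simulated*, but each
simulation returns only a noisy realization of the breeding goal, so the
target function cannot be maximized directly. `breedoptim` implements the
full workflow for breeders and quantitative geneticists who face this
problem:

1. **Search space** — budget-constrained design enumeration and uniform
   sampling under
   `4,000·x1 + 3,000·x2 ≤ 10,000,000`, `100 ≤ x2 ≤ 700`, `3 ≤ x3 ≤ 30`
   (all defaults configurable), with `x1` allocated from the residual
   budget.
2. **Simulator** — a 15-year progeny-testing dairy scheme under the
   infinitesimal model: progeny-test EBVs with accuracy
   `r = sqrt(n·h²/4 / (1+(n−1)·h²/4))`, truncation selection of sires,
   and exact pedigree kinship via the tabular method. One run yields the
   genetic gain `g`, the inbreeding level `f` (mean pairwise kinship of
   the final newborn cohort) and the composite target `m = g − 50·f`.
3. **Smoothing** — a Nadaraya–Watson estimator with a product Gaussian
   kernel, `m̂(x) = Σᵢ yᵢ K((x−xᵢ)/h) / Σᵢ K((x−xᵢ)/h)`, smoothing `g` and
   `f` separately (`f` with bandwidths ÷ 3) and composing
   `m̂ = ĝ − w·f̂`; plus a piecewise-linear interpolation baseline and
   cross-validation bandwidth selection.
4. **Optimizer** — brute-force argmax and local-maxima detection on the
   smoothed surface, iterative search-box narrowing with bandwidth halving
   `(30, 1) → (15, 0.5) → (7.5, 0.25)`, and a convergence rule on the
   stability of the estimated optimum.
5. **Evaluation** — bootstrap comparison of smoothing methods and
   optimum-location stability versus the number of simulations, driven by
   a synthetic noisy objective with a known optimum.

## Worked example

```r
library(breedoptim)

# budget allocation: daughters affordable after housing x2 test bulls
allocateDaughters(c(100, 163, 184))
#> [1] 2425 2377 2362

# one stochastic realization of a small scheme
out <- simulateScheme(c(x1 = 425, x2 = 100, x3 = 10),
                      SchemeConfig(years = 15), seed = 1)
out
#> SimOutcome for (x1=425, x2=100, x3=10): g = 2.228, f = 0.0486, m = -0.204

# full iterative optimization against a synthetic noisy objective whose
# true optimum is at (x2, x3) = (400, 15)
report <- runPipeline(objectiveFunction(quadraticObjective()),
                      nSims = c(2000, 1500, 500), seed = 1)
report
#> OptimizationReport: 3 iteration(s), converged (optimum stable within 1 grid step(s) at iteration 3)
#>   optimum: (x1=2200, x2=399, x3=15), m_hat = 9.6468
```

The realization above illustrates the trade-off the composite target
encodes: the design gains 2.23 genetic standard deviations over 15 years
but accumulates kinship 0.049, so `m = 2.228 − 50 × 0.0486 ≈ −0.20`. The
pipeline output shows the optimizer recovering the constructed optimum to
within one grid step despite unit-variance noise on every realization:
after three iterations with bandwidths halved down to `(7.5, 0.25)`, the
estimated maximum sits at `(x2, x3) = (399, 15)`.

To run the breeding simulator inside the pipeline instead of the synthetic
surface, pass `objectiveFunction(SchemeConfig(), TargetSpec())`. A thin
command-line wrapper with `simulate`, `smooth`, `optimize`, `pipeline` and
`evaluate` subcommands lives in `inst/cli/breedoptim.R`.

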