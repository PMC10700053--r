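# Accessor generics and show methods. Slots are never accessed with @ from
# user code; these accessors are the supported surface.

#' @rdname BudgetModel-class
#' @param object a breedoptim S4 object.
#' @export
setGeneric("totalBudget", function(object) standardGeneric("totalBudget"))
#' @rdname BudgetModel-class
#' @export
setMethod("totalBudget", "BudgetModel", function(object) object@totalBudget)

#' @rdname BudgetModel-class
#' @export
setGeneric("costPerCow", function(object) standardGeneric("costPerCow"))
#' @rdname BudgetModel-class
#' @export
setMethod("costPerCow", "BudgetModel", function(object) object@costPerCow)

#' @rdname BudgetModel-class
#' @export
setGeneric("costPerBull", function(object) standardGeneric("costPerBull"))
#' @rdname BudgetModel-class
#' @export
setMethod("costPerBull", "BudgetModel", function(object) object@costPerBull)

#' @rdname SearchBox-class
#' @param object a breedoptim S4 object.
#' @export
setGeneric("x2Range", function(object) standardGeneric("x2Range"))
#' @rdname SearchBox-class
#' @export
setMethod("x2Range", "SearchBox", function(object) object@x2Range)
#' @rdname SearchBox-class
#' @export
setMethod("x2Range", "ParameterBounds", function(object) c(object@x2Min, object@x2Max))

#' @rdname SearchBox-class
#' @export
setGeneric("x3Range", function(object) standardGeneric("x3Range"))
#' @rdname SearchBox-class
#' @export
setMethod("x3Range", "SearchBox", function(object) object@x3Range)
#' @rdname SearchBox-class
#' @export
setMethod("x3Range", "ParameterBounds", function(object) c(object@x3Min, object@x3Max))

#' Bandwidth values for a given response
#'
#' Returns the per-dimension bandwidth vector used when smoothing the given
#' response: `h` for `g` and `m`, `h * fScale` for `f`.
#'
#' @param object a [Bandwidths-class] object.
#' @param response one of "g", "m", "f".
#' @return named numeric vector of bandwidths.
#' @examples
#' hValues(Bandwidths(), "f")
#' @export
setGeneric("hValues", function(object, response = c("g", "m", "f"))
  standardGeneric("hValues"))
#' @rdname hValues
#' @export
setMethod("hValues", "Bandwidths", function(object, response = c("g", "m", "f")) {
  response <- match.arg(response)
  if (response == "f") object@h * object@fScale else object@h
})

#' @rdname SimOutcome-class
#' @param object a [SimOutcome-class].
#' @export
setGeneric("geneticGain", function(object) standardGeneric("geneticGain"))
#' @rdname SimOutcome-class
#' @export
setMethod("geneticGain", "SimOutcome", function(object) object@g)

#' @rdname SimOutcome-class
#' @export
setGeneric("inbreedingLevel", function(object) standardGeneric("inbreedingLevel"))
#' @rdname SimOutcome-class
#' @export
setMethod("inbreedingLevel", "SimOutcome", function(object) object@f)

#' @rdname SimOutcome-class
#' @export
setGeneric("targetValue", function(object) standardGeneric("targetValue"))
#' @rdname SimOutcome-class
#' @export
setMethod("targetValue", "SimOutcome", function(object) object@m)

#' @rdname SimOutcome-class
#' @export
setGeneric("trajectories", function(object) standardGeneric("trajectories"))
#' @rdname SimOutcome-class
#' @export
setMethod("trajectories", "SimOutcome", function(object)
  data.frame(year = seq_along(object@perYearG), g = object@perYearG,
             f = object@perYearF, sirePathG = object@sirePathG))

#' @rdname SimOutcome-class
#' @export
setGeneric("pedigree", function(object) standardGeneric("pedigree"))
#' @rdname SimOutcome-class
#' @export
setMethod("pedigree", "SimOutcome", function(object) object@pedigree)

#' Export a smoothed surface as a data.frame
#'
#' @param object a [KernelSurface-class].
#' @return data.frame with columns x2, x3, g_hat, f_hat, m_hat, weight_mass,
#'   missing_flag (the delimited-text export layout).
#' @export
setGeneric("surfaceTable", function(object) standardGeneric("surfaceTable"))
#' @rdname surfaceTable
#' @export
setMethod("surfaceTable", "KernelSurface", function(object) {
  data.frame(x2 = object@grid$x2, x3 = object@grid$x3,
             g_hat = object@gHat, f_hat = object@fHat, m_hat = object@mHat,
             weight_mass = object@massG, missing_flag = object@missing)
})

#' @rdname OptimizationReport-class
#' @param object a breedoptim result object.
#' @export
setGeneric("optimum", function(object) standardGeneric("optimum"))
#' @rdname OptimizationReport-class
#' @export
setMethod("optimum", "OptimizationReport", function(object) object@optimum)

#' @rdname OptimizationReport-class
#' @export
setGeneric("iterations", function(object) standardGeneric("iterations"))
#' @rdname OptimizationReport-class
#' @export
setMethod("iterations", "OptimizationReport", function(object) object@iterations)

#' @rdname OptimizationReport-class
#' @export
setGeneric("records", function(object) standardGeneric("records"))
#' @rdname OptimizationReport-class
#' @export
setMethod("records", "OptimizationReport", function(object) object@records)

#' @rdname SyntheticObjective-class
#' @param object a [SyntheticObjective-class].
#' @export
setGeneric("trueArgmax", function(object) standardGeneric("trueArgmax"))
#' @rdname SyntheticObjective-class
#' @export
setMethod("trueArgmax", "SyntheticObjective", function(object) object@argmax)

setMethod("show", "BudgetModel", function(object) {
  cat("BudgetModel:", format(object@totalBudget, big.mark = ","),
      "per year |", object@costPerCow, "per cow,", object@costPerBull,
      "per bull\n")
})

setMethod("show", "ParameterBounds", function(object) {
  cat(sprintf("ParameterBounds: %d <= x2 <= %d, %d <= x3 <= %d\n",
              object@x2Min, object@x2Max, object@x3Min, object@x3Max))
})

setMethod("show", "SearchBox", function(object) {
  cat(sprintf("SearchBox: x2 in [%d, %d], x3 in [%d, %d]\n",
              object@x2Range[1], object@x2Range[2],
              object@x3Range[1], object@x3Range[2]))
})

setMethod("show", "Bandwidths", function(object) {
  cat("Bandwidths (g/m):",
      paste(sprintf("%s=%g", names(object@h), object@h), collapse = ", "),
      sprintf("| f scaled by %g\n", object@fScale))
})

setMethod("show", "KernelSurface", function(object) {
  cat(sprintf("KernelSurface (%s): %d grid points, %d missing\n",
              object@method, nrow(object@grid), sum(object@missing)))
  if (any(!object@missing)) {
    i <- which.max(ifelse(object@missing, -Inf, object@mHat))
    cat(sprintf("  max m_hat = %.4f at (x2=%d, x3=%d)\n", object@mHat[i],
                object@grid$x2[i], object@grid$x3[i]))
  }
})

setMethod("show", "SimOutcome", function(object) {
  cat(sprintf("SimOutcome for (x1=%d, x2=%d, x3=%d): g = %.3f, f = %.4f, m = %.3f\n",
              object@params[1], object@params[2], object@params[3],
              object@g, object@f, object@m))
})

setMethod("show", "OptimizationReport", function(object) {
  cat(sprintf("OptimizationReport: %d iteration(s), %s (%s)\n",
              length(object@iterations),
              if (object@converged) "converged" else "not converged",
              object@reason))
  cat(sprintf("  optimum: (x1=%d, x2=%d, x3=%d), m_hat = %.4f\n",
              object@optimum$par["x1"], object@optimum$par["x2"],
              object@optimum$par["x3"], object@optimum$value))
})

setMethod("show", "ComparisonResult", function(object) {
  cat("ComparisonResult over", length(unique(object@replicates$draw)),
      "bootstrap draws (", object@nFailed, "failed )\n")
  print(object@summary, row.names = FALSE)
})

setMethod("show", "StabilityResult", function(object) {
  cat("StabilityResult: fraction of optima inside region per sample size\n")
  print(object@fractions, row.names = FALSE)
})

setMethod("show", "SyntheticObjective", function(object) {
  cat(sprintf("SyntheticObjective '%s': argmax (x2=%g, x3=%g), noise sd g=%g, f=%g\n",
              object@label, object@argmax[1], object@argmax[2],
              object@noiseSdG, object@noiseSdF))
})
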