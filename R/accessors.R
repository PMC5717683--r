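# Accessors and show methods.

#' @describeIn nNodes Node count of a pattern.
#' @export
setMethod("nNodes", "StructurePattern", function(x) x@n)

#' @describeIn nNodes Node count of a network.
#' @export
setMethod("nNodes", "WeightedNetwork", function(x) nrow(x@weights))

#' @describeIn nNodes Node count of generation criteria.
#' @export
setMethod("nNodes", "GenerationCriteria", function(x) x@n)

#' @describeIn adjacency Weight matrix of a network.
#' @export
setMethod("adjacency", "WeightedNetwork", function(x) x@weights)

#' @describeIn networkPattern Pattern of a network.
#' @export
setMethod("networkPattern", "WeightedNetwork", function(x) x@pattern)

#' @describeIn networkPattern Pattern of generation criteria.
#' @export
setMethod("networkPattern", "GenerationCriteria", function(x) x@pattern)

#' Disconnected pairs of a structural pattern
#'
#' @param pattern A [StructurePattern-class].
#' @return Two-column integer matrix of unordered pairs (\eqn{i < j}).
#' @export
disconnectedPairs <- function(pattern) {
  stopifnot(is(pattern, "StructurePattern"))
  pattern@disconnected
}

#' @describeIn achievedMetrics Achieved metrics.
#' @export
setMethod("achievedMetrics", "GenerationResult", function(x) x@achieved)

#' @describeIn finalNetwork Final network.
#' @export
setMethod("finalNetwork", "GenerationResult", function(x) x@network)

#' @describeIn converged Convergence flag.
#' @export
setMethod("converged", "GenerationResult", function(x) x@converged)

#' @describeIn outerIterations Perturbation count.
#' @export
setMethod("outerIterations", "GenerationResult", function(x) x@outerIterations)

#' @describeIn trajectory Objective trajectory.
#' @export
setMethod("trajectory", "GenerationResult", function(x) x@trajectory)

setMethod("show", "StructurePattern", function(object) {
  cat("StructurePattern:", object@n, "nodes,",
      if (object@symmetric) "symmetric" else "asymmetric", "\n")
  nd <- nrow(object@disconnected)
  if (nd)
    cat("  forced disconnections:", nd, "pair(s)\n")
})

setMethod("show", "WeightedNetwork", function(object) {
  n <- nNodes(object)
  cat("WeightedNetwork:", n, "nodes,",
      freeParameterization(object@pattern)$nFree, "connected pair(s)\n")
  w <- reduceToFreeWeights(object)
  if (length(w))
    cat(sprintf("  weight range: [%.4g, %.4g]\n", min(w), max(w)))
})

setMethod("show", "SpectralSummary", function(object) {
  cat("SpectralSummary:\n")
  cat(sprintf("  spectral radius r = %.6g\n", object@r))
  cat(sprintf("  eigenvector variance v = %.6g\n", object@v))
  if (is.na(object@s))
    cat("  eigenvector skewness s = undefined (homogeneous eigenvector)\n")
  else
    cat(sprintf("  eigenvector skewness s = %.6g\n", object@s))
})

setMethod("show", "EqualitySystem", function(object) {
  tab <- table(factor(object@rowKinds,
                      levels = c("diagonal", "disconnection", "symmetry",
                                 "empty")))
  cat("EqualitySystem: n =", object@n, "(", object@n^2, "x", object@n^2,
      ", row-major vec)\n")
  cat("  rows:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
})

setMethod("show", "GenerationCriteria", function(object) {
  cat("GenerationCriteria: n =", object@n, "\n")
  cat(sprintf("  targets: r* = %g, v* = %g, s* = %s\n", object@rStar,
              object@vStar,
              if (is.na(object@sStar)) "none" else format(object@sStar)))
  cat(sprintf("  omega = (%.4g, %.4g, %.4g); weight box [%g, %g]\n",
              object@omega[1], object@omega[2], object@omega[3],
              object@wMin, object@wMax))
  cat(sprintf("  tol = %g (abs %g), maxOuter = %d, seed = %d\n",
              object@tol, object@tolAbs, object@maxOuter, object@seed))
})

setMethod("show", "GenerationResult", function(object) {
  cat("GenerationResult:",
      if (object@converged) "converged" else "NOT converged",
      "after", object@outerIterations, "perturbation(s)\n")
  show(object@achieved)
})

setMethod("show", "FeasibilityBounds", function(object) {
  cat(sprintf("FeasibilityBounds (n = %d): v in [0, %.6g], |s| <= %.6g\n",
              object@n, object@vMax, object@sBound))
})

setMethod("show", "ConvergenceMap", function(object) {
  cat(sprintf("ConvergenceMap: n = %d, r* = %g, weights in [%g, %g]\n",
              object@n, object@rStar, object@wMin, object@wMax))
  cat("  grid points:", nrow(object@grid), "; converged:",
      sum(object@grid$converged), "\n")
})
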