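#' Number of nodes
#'
#' @param x A [StructurePattern-class], [WeightedNetwork-class],
#'   [GenerationCriteria-class] or similar object.
#' @return Integer node count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Adjacency (weight) matrix of a network
#'
#' @param x A [WeightedNetwork-class].
#' @return The numeric weight matrix.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' Structural pattern of an object
#'
#' @param x A [WeightedNetwork-class] or [GenerationCriteria-class].
#' @return A [StructurePattern-class].
#' @export
setGeneric("networkPattern", function(x) standardGeneric("networkPattern"))

#' Spectral radius
#'
#' The largest eigenvalue \eqn{r = \max\{\lambda_1, \ldots, \lambda_n\}} of
#' the adjacency matrix. For a symmetric nonnegative matrix this is real and
#' nonnegative (Perron-Frobenius).
#'
#' @param x A [WeightedNetwork-class], numeric matrix, or
#'   [SpectralSummary-class].
#' @return The spectral radius (single number).
#' @examples
#' spectralRadius(completeUniform(6, 16))  # (n-1) * w = 80
#' @export
setGeneric("spectralRadius", function(x) standardGeneric("spectralRadius"))

#' Dominant (Perron) eigenvector
#'
#' The eigenvector of the spectral radius, normalised to unit Euclidean norm
#' with nonnegative orientation. Requires the underlying undirected graph of
#' nonzero weights to be connected (irreducible matrix), which guarantees a
#' unique, strictly positive dominant eigenvector.
#'
#' @param x A [WeightedNetwork-class], numeric matrix, or
#'   [SpectralSummary-class].
#' @return Numeric vector of node connectivity scores.
#' @export
setGeneric("dominantEigenvector",
           function(x) standardGeneric("dominantEigenvector"))

#' Population variance of eigenvector elements
#'
#' \eqn{v = (1/n) \sum_k (x_k - \langle x\rangle)^2}; population (divide by
#' \eqn{n}), not sample, moments.
#'
#' @param x Numeric vector or [SpectralSummary-class].
#' @return The population variance.
#' @examples
#' eigvecVariance(c(1, 0, 0, 0))  # 3/16
#' @export
setGeneric("eigvecVariance", function(x) standardGeneric("eigvecVariance"))

#' Population skewness of eigenvector elements
#'
#' Computed by the moment expansion
#' \deqn{s = \frac{(1/n)\sum_k x_k^3 - 3\langle x\rangle v - \langle
#'   x\rangle^3}{v^{3/2}},}
#' algebraically equal to the standardised third central moment. Undefined
#' (error) for a homogeneous vector (\eqn{v = 0}).
#'
#' @param x Numeric vector or [SpectralSummary-class].
#' @return The population skewness.
#' @examples
#' eigvecSkewness(c(1, 0, 0, 0, 0))  # (n-2)/sqrt(n-1) = 1.5
#' @export
setGeneric("eigvecSkewness", function(x) standardGeneric("eigvecSkewness"))

#' Achieved metrics of a generation result
#'
#' @param x A [GenerationResult-class].
#' @return The [SpectralSummary-class] of the final network.
#' @export
setGeneric("achievedMetrics", function(x) standardGeneric("achievedMetrics"))

#' Final network of a generation result
#'
#' @param x A [GenerationResult-class].
#' @return The [WeightedNetwork-class].
#' @export
setGeneric("finalNetwork", function(x) standardGeneric("finalNetwork"))

#' Convergence flag of a generation result
#'
#' @param x A [GenerationResult-class].
#' @return Logical.
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' Outer (perturbation) iteration count of a generation result
#'
#' @param x A [GenerationResult-class].
#' @return Integer.
#' @export
setGeneric("outerIterations", function(x) standardGeneric("outerIterations"))

#' Objective / metric-difference trajectory of a generation run
#'
#' @param x A [GenerationResult-class].
#' @return Data frame with columns `iteration`, `objective`, `dr`, `dv`, `ds`.
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))
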