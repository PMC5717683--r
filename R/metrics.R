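# Spectral metrics: spectral radius and the population variance / skewness
# of the dominant eigenvector. These are the three quantities the generator
# targets.

.checkMatrixInput <- function(A) {
  if (!is.matrix(A) || !is.numeric(A))
    stop("input must be a numeric matrix", call. = FALSE)
  if (nrow(A) != ncol(A))
    stop("input matrix must be square, got ", nrow(A), " x ", ncol(A),
         call. = FALSE)
  if (anyNA(A))
    stop("input matrix contains NA/NaN", call. = FALSE)
  invisible(A)
}

.isConnectedMatrix <- function(A) {
  g <- igraph::graph_from_adjacency_matrix((A != 0) * 1, mode = "max")
  igraph::is_connected(g)
}

## Full symmetric eigendecomposition; dominant pair with nonnegative
## orientation. All network sizes of interest are small (n <= 500), so no
## sparse/iterative path is used.
.eigDominant <- function(A, checkConnected = TRUE, checkSimple = TRUE) {
  .checkMatrixInput(A)
  if (checkConnected && !.isConnectedMatrix(A))
    stop("dominant eigenvector not unique / not strictly positive: ",
         "the nonzero pattern is disconnected (Perron-Frobenius requires ",
         "an irreducible matrix)", call. = FALSE)
  e <- eigen(A, symmetric = TRUE)
  r <- e$values[1]
  if (checkSimple && length(e$values) > 1 &&
      (r - e$values[2]) <= 1e-12 * max(1, abs(r)))
    stop("dominant eigenvalue is not simple (multiplicity > 1); ",
         "the dominant eigenvector is not uniquely defined", call. = FALSE)
  x <- e$vectors[, 1]
  if (sum(x) < 0) x <- -x
  ## clip the tiny negative round-off a strictly positive Perron vector can
  ## acquire from the dense solver
  x[x < 0 & x > -1e-12] <- 0
  e$vectors[, 1] <- x
  list(r = r, x = x, values = e$values, vectors = e$vectors)
}

#' @describeIn spectralRadius Largest eigenvalue of the weight matrix.
#' @export
setMethod("spectralRadius", "matrix", function(x) {
  .checkMatrixInput(x)
  vals <- eigen(x, symmetric = isSymmetric(x), only.values = TRUE)$values
  ## for a nonnegative matrix the dominant eigenvalue is real
  ## (Perron-Frobenius); Re() discards round-off imaginary parts in the
  ## asymmetric case
  max(Re(vals))
})

#' @describeIn spectralRadius Spectral radius of a network.
#' @export
setMethod("spectralRadius", "WeightedNetwork", function(x) {
  spectralRadius(x@weights)
})

#' @describeIn spectralRadius Stored spectral radius of a summary.
#' @export
setMethod("spectralRadius", "SpectralSummary", function(x) x@r)

#' @describeIn dominantEigenvector Perron eigenvector of a matrix.
#' @export
setMethod("dominantEigenvector", "matrix", function(x) {
  .eigDominant(x)$x
})

#' @describeIn dominantEigenvector Perron eigenvector of a network.
#' @export
setMethod("dominantEigenvector", "WeightedNetwork", function(x) {
  .eigDominant(x@weights)$x
})

#' @describeIn dominantEigenvector Stored eigenvector of a summary.
#' @export
setMethod("dominantEigenvector", "SpectralSummary", function(x) x@eigenvector)

.popVariance <- function(x) {
  if (length(x) == 0)
    stop("variance of an empty vector is undefined", call. = FALSE)
  if (anyNA(x)) stop("vector contains NA", call. = FALSE)
  m <- mean(x)
  mean((x - m)^2)
}

.popSkewness <- function(x) {
  v <- .popVariance(x)
  if (v < .V_EPS)
    stop("skewness undefined for homogeneous vector (variance is zero)",
         call. = FALSE)
  m <- mean(x)
  (mean(x^3) - 3 * m * v - m^3) / v^1.5
}

#' @describeIn eigvecVariance Population variance of a numeric vector.
#' @export
setMethod("eigvecVariance", "numeric", function(x) .popVariance(x))

#' @describeIn eigvecVariance Stored variance of a summary.
#' @export
setMethod("eigvecVariance", "SpectralSummary", function(x) x@v)

#' @describeIn eigvecSkewness Population skewness of a numeric vector.
#' @export
setMethod("eigvecSkewness", "numeric", function(x) .popSkewness(x))

#' @describeIn eigvecSkewness Stored skewness of a summary (`NA` when the
#'   eigenvector is homogeneous).
#' @export
setMethod("eigvecSkewness", "SpectralSummary", function(x) x@s)

#' Summarise the spectral metrics of a network
#'
#' Computes the spectral radius and the unit-norm nonnegative dominant
#' eigenvector of a connected network, together with the population mean,
#' variance and skewness of the eigenvector elements. Skewness is reported
#' as `NA` when the eigenvector is homogeneous (variance zero), e.g. for a
#' uniform complete network.
#'
#' @param net A [WeightedNetwork-class] (or square numeric matrix).
#' @return A [SpectralSummary-class].
#' @examples
#' spectralSummary(completeUniform(6, 16))  # r = 80, v = 0, s undefined
#' @export
spectralSummary <- function(net) {
  A <- if (is(net, "WeightedNetwork")) net@weights else net
  ed <- .eigDominant(A)
  x <- ed$x
  m <- mean(x)
  v <- .popVariance(x)
  s <- if (v < .V_EPS) NA_real_ else .popSkewness(x)
  new("SpectralSummary", r = ed$r, eigenvector = x, mean = m, v = v, s = s)
}
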