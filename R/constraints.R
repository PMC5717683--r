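# Equality-constraint system B a = E over the row-major vectorisation of A:
# zero diagonal, forced disconnections, symmetry. The optimizer never solves
# this system directly -- it works in the free parameterization, which
# satisfies the constraints by construction -- but B and E are retained as
# the ground-truth validator for every emitted matrix.

## row-major vec index of entry (i, j) of an n x n matrix
.vecIndex <- function(i, j, n) (i - 1L) * n + j

## row-major vectorisation
.vecRowMajor <- function(A) as.vector(t(A))

#' Build the equality-constraint system for a structural pattern
#'
#' Constructs the sparse \eqn{n^2 \times n^2} system \eqn{B a = E} acting on
#' the row-major vectorisation \eqn{a} of the adjacency matrix:
#' \itemize{
#'   \item one \emph{diagonal} row per node, forcing \eqn{a_{ii} = 0};
#'   \item two \emph{disconnection} rows per forced-zero pair, forcing
#'     \eqn{a_{ij} = 0} and \eqn{a_{ji} = 0};
#'   \item for symmetric patterns, one \emph{symmetry} row per connected
#'     unordered pair, with coefficients \eqn{+1} at \eqn{a_{ij}} and
#'     \eqn{-1} at \eqn{a_{ji}}, forcing \eqn{a_{ij} = a_{ji}}.
#' }
#' All remaining rows are empty (all-zero), so the system always has
#' \eqn{n^2} rows ("at most \eqn{n^2} equations"). The right-hand side
#' \eqn{E} is the zero vector for every rule above.
#'
#' @param pattern A [StructurePattern-class].
#' @return An [EqualitySystem-class].
#' @examples
#' sys <- buildEqualitySystem(structurePattern(3))
#' table(rowKinds(sys))  # 3 diagonal + 3 symmetry + 3 empty
#' @export
buildEqualitySystem <- function(pattern) {
  stopifnot(is(pattern, "StructurePattern"))
  validObject(pattern)
  n <- pattern@n
  n2 <- n * n
  ri <- integer(0); ci <- integer(0); xv <- numeric(0)
  kinds <- rep("empty", n2)
  row <- 0L
  for (i in seq_len(n)) {                       # diagonal rows
    row <- row + 1L
    ri <- c(ri, row); ci <- c(ci, .vecIndex(i, i, n)); xv <- c(xv, 1)
    kinds[row] <- "diagonal"
  }
  d <- pattern@disconnected
  for (k in seq_len(nrow(d))) {                 # disconnection rows (pairs)
    i <- d[k, 1]; j <- d[k, 2]
    row <- row + 1L
    ri <- c(ri, row); ci <- c(ci, .vecIndex(i, j, n)); xv <- c(xv, 1)
    kinds[row] <- "disconnection"
    row <- row + 1L
    ri <- c(ri, row); ci <- c(ci, .vecIndex(j, i, n)); xv <- c(xv, 1)
    kinds[row] <- "disconnection"
  }
  if (pattern@symmetric) {                      # symmetry rows
    fp <- freeParameterization(pattern)
    for (k in seq_len(fp$nFree)) {
      i <- fp$iu[k]; j <- fp$ju[k]
      row <- row + 1L
      ri <- c(ri, row, row)
      ci <- c(ci, .vecIndex(i, j, n), .vecIndex(j, i, n))
      xv <- c(xv, 1, -1)
      kinds[row] <- "symmetry"
    }
  }
  B <- Matrix::sparseMatrix(i = ri, j = ci, x = xv, dims = c(n2, n2))
  new("EqualitySystem", B = B, E = numeric(n2), rowKinds = kinds,
      n = n, vecOrder = "row-major")
}

#' Row labels of an equality system
#'
#' @param system An [EqualitySystem-class].
#' @return Character vector with one label per row: `"diagonal"`,
#'   `"disconnection"`, `"symmetry"` or `"empty"`.
#' @export
rowKinds <- function(system) {
  stopifnot(is(system, "EqualitySystem"))
  system@rowKinds
}

#' Check a network against an equality system
#'
#' @param system An [EqualitySystem-class].
#' @param net A [WeightedNetwork-class] or square numeric matrix.
#' @param tol Tolerance on the max-norm residual
#'   \eqn{\|B a - E\|_\infty}.
#' @return `TRUE` iff the residual is within `tol`.
#' @export
satisfiesConstraints <- function(system, net, tol = 1e-9) {
  stopifnot(is(system, "EqualitySystem"))
  A <- if (is(net, "WeightedNetwork")) net@weights else net
  .checkMatrixInput(A)
  if (nrow(A) != system@n)
    stop("dimension mismatch: system is for n = ", system@n,
         ", matrix is ", nrow(A), " x ", ncol(A), call. = FALSE)
  resid <- as.numeric(system@B %*% .vecRowMajor(A)) - system@E
  max(abs(resid)) <= tol
}

#' Free parameterization of constraint-satisfying matrices
#'
#' For a symmetric pattern, the matrices satisfying the equality constraints
#' are exactly those determined by one free weight per \emph{connected}
#' unordered pair (upper-triangle pairs not marked disconnected). This
#' bijection lets the optimizer eliminate the constraints by construction.
#'
#' @param pattern A [StructurePattern-class].
#' @return A list with integer vectors `iu`, `ju` (row/column of each free
#'   pair, \eqn{i < j}) and `nFree`.
#' @examples
#' freeParameterization(structurePattern(6))$nFree  # n(n-1)/2 = 15
#' @export
freeParameterization <- function(pattern) {
  stopifnot(is(pattern, "StructurePattern"))
  n <- pattern@n
  iu <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  ju <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  if (nrow(pattern@disconnected) > 0) {
    keys <- paste(iu, ju)
    drop <- keys %in% paste(pattern@disconnected[, 1], pattern@disconnected[, 2])
    iu <- iu[!drop]; ju <- ju[!drop]
  }
  list(iu = as.integer(iu), ju = as.integer(ju), nFree = length(iu))
}

#' Expand free weights into a conforming network
#'
#' Inverse of [reduceToFreeWeights()]: places each free weight at its
#' \eqn{(i, j)} and \eqn{(j, i)} positions, leaving the diagonal and the
#' disconnected pairs at zero. The result satisfies the equality constraints
#' exactly.
#'
#' @param theta Numeric vector of free weights, in the order of
#'   [freeParameterization()].
#' @param pattern A [StructurePattern-class].
#' @return A [WeightedNetwork-class].
#' @export
expandFreeWeights <- function(theta, pattern) {
  fp <- freeParameterization(pattern)
  if (length(theta) != fp$nFree)
    stop("expected ", fp$nFree, " free weights, got ", length(theta),
         call. = FALSE)
  n <- pattern@n
  A <- matrix(0, n, n)
  A[cbind(fp$iu, fp$ju)] <- theta
  A[cbind(fp$ju, fp$iu)] <- theta
  new("WeightedNetwork", weights = A, pattern = pattern)
}

#' Reduce a conforming network to its free weights
#'
#' @param net A [WeightedNetwork-class] whose pattern is symmetric.
#' @return Numeric vector of free weights (upper-triangle connected pairs).
#' @export
reduceToFreeWeights <- function(net) {
  stopifnot(is(net, "WeightedNetwork"))
  fp <- freeParameterization(net@pattern)
  net@weights[cbind(fp$iu, fp$ju)]
}
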