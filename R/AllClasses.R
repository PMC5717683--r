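#' @import methods
#' @importFrom stats runif optim setNames
#' @importFrom utils read.table write.table
NULL

## tolerance below which an eigenvector is treated as homogeneous (variance
## indistinguishable from 0 at double precision for unit-norm vectors)
.V_EPS <- 1e-24

# ---------------------------------------------------------------------------
# StructurePattern
# ---------------------------------------------------------------------------

#' Structural pattern of a weighted network
#'
#' Records the node count, the set of unordered node pairs forced to be
#' disconnected (weight exactly zero), and whether the network is symmetric
#' (undirected). The pattern is the structural side of the equality
#' constraints: together with the zero diagonal it determines which entries
#' of the adjacency matrix are free.
#'
#' @slot n Integer node count (>= 2).
#' @slot disconnected Integer matrix with two columns; each row is an
#'   unordered pair \eqn{i < j} forced to weight 0.
#' @slot symmetric Logical; when `TRUE` the matrix must satisfy
#'   \eqn{a_{ij} = a_{ji}}.
#'
#' @seealso [structurePattern()], [buildEqualitySystem()]
#' @export
setClass("StructurePattern",
  representation(
    n = "integer",
    disconnected = "matrix",
    symmetric = "logical"
  ),
  prototype(
    n = 2L,
    disconnected = matrix(integer(0), 0, 2),
    symmetric = TRUE
  )
)

setValidity("StructurePattern", function(object) {
  msg <- character(0)
  if (length(object@n) != 1L || is.na(object@n) || object@n < 2L)
    msg <- c(msg, "n must be a single integer >= 2")
  d <- object@disconnected
  if (ncol(d) != 2L)
    msg <- c(msg, "disconnected must have two columns")
  if (nrow(d) > 0) {
    if (!is.numeric(d) || anyNA(d))
      msg <- c(msg, "disconnected pairs must be non-missing integers")
    else {
      if (any(d < 1L) || any(d > object@n))
        msg <- c(msg, "disconnected pairs reference node indices outside 1..n")
      if (any(d[, 1] == d[, 2]))
        msg <- c(msg, "a pair (i, i) cannot be marked disconnected (the diagonal is already forced to zero)")
      if (any(d[, 1] > d[, 2]))
        msg <- c(msg, "disconnected pairs must be stored with i < j")
      if (anyDuplicated(paste(d[, 1], d[, 2])))
        msg <- c(msg, "duplicate disconnected pairs")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Create a structural pattern
#'
#' @param n Node count (integer >= 2).
#' @param disconnected Unordered node pairs forced to weight zero, as a
#'   two-column matrix (or `NULL` for a fully connected pattern). Pairs may
#'   be given in either order; they are stored with \eqn{i < j}.
#' @param symmetric Logical; undirected (symmetric) network. Generation is
#'   only supported for symmetric patterns.
#'
#' @return A [StructurePattern-class] object.
#' @examples
#' structurePattern(4)
#' structurePattern(4, disconnected = rbind(c(1, 2)))
#' @export
structurePattern <- function(n, disconnected = NULL, symmetric = TRUE) {
  n <- as.integer(n)
  if (is.null(disconnected)) {
    d <- matrix(integer(0), 0, 2)
  } else {
    d <- matrix(as.integer(disconnected), ncol = 2)
    d <- cbind(pmin(d[, 1], d[, 2]), pmax(d[, 1], d[, 2]))
    d <- unique(d)
    d <- d[order(d[, 1], d[, 2]), , drop = FALSE]
  }
  new("StructurePattern", n = n, disconnected = d, symmetric = symmetric)
}

# ---------------------------------------------------------------------------
# WeightedNetwork
# ---------------------------------------------------------------------------

#' Weighted network (adjacency matrix with structural pattern)
#'
#' A square \eqn{n \times n} nonnegative weight matrix \eqn{A} with zero
#' diagonal. Entry \eqn{a_{ij}} is the weight (in the motivating habitat
#' graphs, the cost of movement) between nodes \eqn{i} and \eqn{j}. The
#' attached [StructurePattern-class] records forced disconnections and the
#' symmetry flag.
#'
#' @slot weights Numeric \eqn{n \times n} matrix.
#' @slot pattern A [StructurePattern-class].
#'
#' @seealso [weightedNetwork()], [spectralSummary()], [adjacency()]
#' @export
setClass("WeightedNetwork",
  representation(
    weights = "matrix",
    pattern = "StructurePattern"
  )
)

setValidity("WeightedNetwork", function(object) {
  msg <- character(0)
  A <- object@weights
  if (!is.numeric(A) || nrow(A) != ncol(A))
    return("weights must be a square numeric matrix")
  if (anyNA(A))
    return("weights contain NA/NaN")
  n <- nrow(A)
  if (n != object@pattern@n)
    msg <- c(msg, "pattern node count does not match matrix dimension")
  if (any(diag(A) != 0))
    msg <- c(msg, "diagonal entries must all be exactly 0")
  if (any(A < 0))
    msg <- c(msg, "off-diagonal entries must be >= 0")
  if (object@pattern@symmetric && !identical(A, t(A)))
    msg <- c(msg, "matrix must be exactly symmetric for a symmetric pattern")
  d <- object@pattern@disconnected
  if (nrow(d) > 0 && n == object@pattern@n) {
    if (any(A[d] != 0) || any(A[d[, c(2, 1), drop = FALSE]] != 0))
      msg <- c(msg, "entries marked disconnected in the pattern must be exactly 0")
  }
  if (length(msg)) msg else TRUE
})

#' Create a weighted network from a matrix
#'
#' @param weights Square numeric matrix: nonnegative, zero diagonal. For a
#'   symmetric pattern the matrix is symmetrised bit-exactly from its upper
#'   triangle if `enforceSymmetry = TRUE`, otherwise it must already be
#'   exactly symmetric.
#' @param pattern Optional [StructurePattern-class]. By default, off-diagonal
#'   zero pairs are recorded as structural disconnections.
#' @param symmetric Used only when `pattern` is `NULL`.
#' @param enforceSymmetry Copy the upper triangle onto the lower one before
#'   validation (convenient for matrices that are symmetric only to rounding).
#'
#' @return A [WeightedNetwork-class] object.
#' @examples
#' A <- matrix(c(0, 2, 2, 0), 2, 2)
#' weightedNetwork(A)
#' @export
weightedNetwork <- function(weights, pattern = NULL, symmetric = TRUE,
                            enforceSymmetry = FALSE) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  dimnames(weights) <- NULL
  if (is.null(pattern)) {
    n <- nrow(weights)
    zeros <- which(weights == 0 & t(weights) == 0 &
                     row(weights) < col(weights), arr.ind = TRUE)
    pattern <- structurePattern(n,
      disconnected = if (nrow(zeros)) zeros else NULL,
      symmetric = symmetric)
  }
  if (pattern@symmetric && enforceSymmetry) {
    weights[lower.tri(weights)] <- t(weights)[lower.tri(weights)]
  }
  new("WeightedNetwork", weights = weights, pattern = pattern)
}

# ---------------------------------------------------------------------------
# SpectralSummary
# ---------------------------------------------------------------------------

#' Spectral summary of a weighted network
#'
#' Bundles the three metrics the generator targets: the spectral radius
#' \eqn{r} (largest eigenvalue of the adjacency matrix), and the variance
#' \eqn{v} and skewness \eqn{s} of the elements of the dominant (Perron)
#' eigenvector, normalised to unit Euclidean norm with nonnegative
#' orientation. Moments are population moments (divide by \eqn{n}).
#' Skewness is `NA` when the eigenvector is homogeneous (\eqn{v = 0}).
#'
#' @slot r Spectral radius.
#' @slot eigenvector Unit-norm nonnegative dominant eigenvector.
#' @slot mean Mean of the eigenvector elements.
#' @slot v Population variance of the eigenvector elements.
#' @slot s Population skewness (`NA_real_` when undefined).
#'
#' @seealso [spectralSummary()], [spectralRadius()], [eigvecVariance()]
#' @export
setClass("SpectralSummary",
  representation(
    r = "numeric",
    eigenvector = "numeric",
    mean = "numeric",
    v = "numeric",
    s = "numeric"
  )
)

setValidity("SpectralSummary", function(object) {
  msg <- character(0)
  if (length(object@r) != 1L || is.na(object@r) || object@r < 0)
    msg <- c(msg, "r must be a single nonnegative number")
  x <- object@eigenvector
  if (length(x) < 1L || anyNA(x) || any(x < -1e-12))
    msg <- c(msg, "eigenvector must be nonnegative")
  if (abs(sum(x^2) - 1) > 1e-8)
    msg <- c(msg, "eigenvector must have unit Euclidean norm")
  if (length(object@v) != 1L || is.na(object@v) || object@v < 0)
    msg <- c(msg, "v must be a single nonnegative number")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# EqualitySystem
# ---------------------------------------------------------------------------

#' Equality-constraint system B a = E
#'
#' The linear system encoding the structural rules every candidate adjacency
#' matrix must satisfy: zero diagonal (\eqn{a_{ii} = 0}), forced
#' disconnections (\eqn{a_{ij} = a_{ji} = 0}) and, for symmetric patterns,
#' symmetry (\eqn{a_{ij} - a_{ji} = 0}). `B` is a sparse
#' \eqn{n^2 \times n^2} coefficient matrix acting on the row-major
#' vectorisation of \eqn{A}; `E` is the right-hand side (all-zero for the
#' rules above); rows not used by any rule are empty (all-zero).
#'
#' @slot B Sparse coefficient matrix (`Matrix::sparseMatrix`).
#' @slot E Numeric right-hand side of length \eqn{n^2}.
#' @slot rowKinds Character label per row: `"diagonal"`, `"disconnection"`,
#'   `"symmetry"` or `"empty"`.
#' @slot n Node count.
#' @slot vecOrder Vectorisation order of \eqn{A} (always `"row-major"`).
#'
#' @seealso [buildEqualitySystem()], [satisfiesConstraints()]
#' @export
setClass("EqualitySystem",
  representation(
    B = "Matrix",
    E = "numeric",
    rowKinds = "character",
    n = "integer",
    vecOrder = "character"
  )
)

setValidity("EqualitySystem", function(object) {
  n2 <- as.numeric(object@n)^2
  msg <- character(0)
  if (nrow(object@B) != n2 || ncol(object@B) != n2)
    msg <- c(msg, "B must be n^2 x n^2")
  if (length(object@E) != n2)
    msg <- c(msg, "E must have length n^2")
  if (length(object@rowKinds) != n2)
    msg <- c(msg, "rowKinds must have length n^2")
  if (!identical(object@vecOrder, "row-major"))
    msg <- c(msg, "vecOrder must be \"row-major\"")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# GenerationCriteria
# ---------------------------------------------------------------------------

#' Criteria for network generation
#'
#' User-defined targets and algorithm settings for [generateNetwork()]:
#' the target spectral radius \eqn{r^*}, eigenvector variance \eqn{v^*} and
#' (optionally) skewness \eqn{s^*}; the objective weights
#' \eqn{\omega_1..\omega_3}; the weight box \eqn{[w_{min}, w_{max}]} used
#' for random draws; convergence tolerances; iteration caps; RNG seed; and
#' the structural pattern.
#'
#' The objective weights default to scale-normalised values
#' \eqn{\omega_k = 1 / \max(t_k^2, f_k^2)} with scale floors
#' \eqn{f = (1, 0.01, 0.01)} for \eqn{(r, v, s)}, so that targets of very
#' different magnitude (e.g. \eqn{r^* = 80} and \eqn{v^* = 0.005})
#' contribute comparably, and a zero target does not blow the weight up.
#'
#' Convergence is per metric: relative difference \eqn{\le} `tol` when the
#' target magnitude is at least `tolAbs`, absolute difference \eqn{\le}
#' `tolAbs` otherwise.
#'
#' @slot n Node count.
#' @slot rStar Target spectral radius (> 0).
#' @slot vStar Target eigenvector variance (>= 0).
#' @slot sStar Target eigenvector skewness, or `NA_real_` when skewness is
#'   not a criterion.
#' @slot omega Nonnegative objective weights \eqn{(\omega_1, \omega_2,
#'   \omega_3)}, not all zero.
#' @slot wMin,wMax Box bounds for randomly drawn weights (0 < wMin <= wMax).
#' @slot wFloor Positive lower bound used by the inner minimiser (see
#'   [minimizeStep()]); defaults to `1e-8 * wMax`.
#' @slot tol Relative convergence tolerance per metric.
#' @slot tolAbs Absolute fallback tolerance for targets of magnitude below
#'   `tolAbs`.
#' @slot maxOuter Cap on hill-climb perturbations.
#' @slot maxInner Iteration cap for the inner minimiser.
#' @slot seed RNG seed.
#' @slot pattern [StructurePattern-class] of the network to generate.
#'
#' @seealso [generationCriteria()], [generateNetwork()], [validateCriteria()]
#' @export
setClass("GenerationCriteria",
  representation(
    n = "integer",
    rStar = "numeric",
    vStar = "numeric",
    sStar = "numeric",
    omega = "numeric",
    wMin = "numeric",
    wMax = "numeric",
    wFloor = "numeric",
    tol = "numeric",
    tolAbs = "numeric",
    maxOuter = "integer",
    maxInner = "integer",
    seed = "integer",
    pattern = "StructurePattern"
  )
)

setValidity("GenerationCriteria", function(object) {
  msg <- character(0)
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (object@n != object@pattern@n)
    msg <- c(msg, "pattern node count does not match n")
  if (!object@pattern@symmetric)
    msg <- c(msg, "generation is only supported for symmetric patterns")
  if (is.na(object@rStar) || object@rStar <= 0)
    msg <- c(msg, "rStar must be > 0")
  if (is.na(object@vStar) || object@vStar < 0)
    msg <- c(msg, "vStar must be >= 0")
  if (length(object@omega) != 3L || anyNA(object@omega) || any(object@omega < 0))
    msg <- c(msg, "omega must be three nonnegative weights")
  else if (all(object@omega == 0))
    msg <- c(msg, "omega must not be all zero")
  if (is.na(object@wMin) || object@wMin <= 0 || object@wMin > object@wMax)
    msg <- c(msg, "need 0 < wMin <= wMax")
  if (object@wFloor <= 0)
    msg <- c(msg, "wFloor must be > 0 (connectivity must be preserved)")
  if (object@tol <= 0 || object@tolAbs <= 0)
    msg <- c(msg, "tolerances must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create generation criteria
#'
#' @param n Node count.
#' @param rStar Target spectral radius.
#' @param vStar Target eigenvector variance.
#' @param sStar Target eigenvector skewness; `NA` (default) drops the
#'   skewness criterion (\eqn{\omega_3 = 0}).
#' @param omega Objective weights; `NULL` (default) uses the
#'   scale-normalised defaults described in [GenerationCriteria-class].
#' @param wMin,wMax Weight box for random draws (defaults 1 and 50).
#' @param wFloor Inner-minimiser lower bound; default `1e-8 * wMax`.
#' @param tol Relative convergence tolerance (default 1\%).
#' @param tolAbs Absolute tolerance for near-zero targets (default 0.01).
#' @param maxOuter Perturbation cap (default 500).
#' @param maxInner Inner-solver iteration cap (default 2000).
#' @param seed RNG seed (default 1).
#' @param pattern Structural pattern; default fully connected symmetric.
#'
#' @return A [GenerationCriteria-class] object.
#' @examples
#' generationCriteria(6, rStar = 80, vStar = 0.026, sStar = 0)
#' @export
generationCriteria <- function(n, rStar, vStar, sStar = NA_real_,
                               omega = NULL, wMin = 1, wMax = 50,
                               wFloor = 1e-8 * wMax,
                               tol = 0.01, tolAbs = 0.01,
                               maxOuter = 500L, maxInner = 2000L,
                               seed = 1L, pattern = NULL) {
  n <- as.integer(n)
  if (is.null(pattern)) pattern <- structurePattern(n)
  if (is.null(omega)) {
    targets <- c(rStar, vStar, if (is.na(sStar)) 0 else sStar)
    floors <- c(1, 0.01, 0.01)
    omega <- 1 / pmax(targets^2, floors^2)
    if (is.na(sStar)) omega[3] <- 0
  }
  new("GenerationCriteria",
    n = n, rStar = as.numeric(rStar), vStar = as.numeric(vStar),
    sStar = as.numeric(sStar), omega = as.numeric(omega),
    wMin = as.numeric(wMin), wMax = as.numeric(wMax),
    wFloor = as.numeric(wFloor),
    tol = as.numeric(tol), tolAbs = as.numeric(tolAbs),
    maxOuter = as.integer(maxOuter), maxInner = as.integer(maxInner),
    seed = as.integer(seed), pattern = pattern)
}

# ---------------------------------------------------------------------------
# GenerationResult
# ---------------------------------------------------------------------------

#' Result of a generation run
#'
#' @slot network The final [WeightedNetwork-class].
#' @slot achieved [SpectralSummary-class] of the final network.
#' @slot criteria The [GenerationCriteria-class] used.
#' @slot converged Logical: did every metric difference fall below its
#'   tolerance.
#' @slot outerIterations Number of hill-climb perturbations performed before
#'   stopping (0 when the first minimisation already satisfied the
#'   tolerances).
#' @slot trajectory Data frame with one row per outer iteration: `iteration`,
#'   `objective`, and the per-metric differences `dr`, `dv`, `ds`.
#'
#' @seealso [generateNetwork()], [trajectory()], [achievedMetrics()]
#' @export
setClass("GenerationResult",
  representation(
    network = "WeightedNetwork",
    achieved = "SpectralSummary",
    criteria = "GenerationCriteria",
    converged = "logical",
    outerIterations = "integer",
    trajectory = "data.frame"
  )
)

# ---------------------------------------------------------------------------
# FeasibilityBounds
# ---------------------------------------------------------------------------

#' Attainable bounds on the eigenvector moments
#'
#' For a unit-Euclidean-norm nonnegative vector of length \eqn{n} the
#' population variance satisfies \eqn{v = 1/n - \langle x\rangle^2 \le
#' (n-1)/n^2}, and the population skewness of any \eqn{n} numbers satisfies
#' \eqn{|s| \le (n-2)/\sqrt{n-1}}. These bounds are derived from the
#' normalisation convention, not transcribed from elsewhere.
#'
#' @slot n Node count.
#' @slot vMax Supremum of the eigenvector variance, \eqn{(n-1)/n^2}.
#' @slot sBound Extremal absolute skewness, \eqn{(n-2)/\sqrt{n-1}}.
#'
#' @seealso [feasibilityBounds()], [validateCriteria()]
#' @export
setClass("FeasibilityBounds",
  representation(n = "integer", vMax = "numeric", sBound = "numeric")
)

# ---------------------------------------------------------------------------
# ConvergenceMap
# ---------------------------------------------------------------------------

#' Convergence map over a (v*, s*) grid
#'
#' Records, for each combination of target variance and skewness at a fixed
#' target spectral radius and weight box, whether the generator converged
#' and the metrics it achieved.
#'
#' @slot rStar Target spectral radius shared by all grid points.
#' @slot n Node count.
#' @slot wMin,wMax Weight box.
#' @slot grid Data frame with columns `v_star`, `s_star`, `converged`,
#'   `r_achieved`, `v_achieved`, `s_achieved`, `outer_iterations`,
#'   `violation`.
#'
#' @seealso [feasibilityMap()], [writeConvergenceMap()]
#' @export
setClass("ConvergenceMap",
  representation(
    rStar = "numeric",
    n = "integer",
    wMin = "numeric",
    wMax = "numeric",
    grid = "data.frame"
  )
)
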