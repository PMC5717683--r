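# Analytic fixture networks. Their spectra are known in closed form, which
# makes them independent oracles for the dense eigensolver, and
# randomConforming() supplies reproducible random instances.

#' Complete network with uniform weights
#'
#' Every off-diagonal entry equals `w`. Closed form: spectral radius
#' \eqn{r = (n-1) w}, uniform dominant eigenvector (\eqn{x_k = 1/\sqrt n}),
#' eigenvector variance 0, skewness undefined.
#'
#' @param n Node count (>= 2).
#' @param w Common weight (> 0).
#' @return A [WeightedNetwork-class].
#' @examples
#' spectralRadius(completeUniform(6, 16))  # 80
#' @export
completeUniform <- function(n, w) {
  stopifnot(n >= 2, w > 0)
  A <- matrix(w, n, n)
  diag(A) <- 0
  weightedNetwork(A)
}

#' Ring (cycle) network with uniform weights
#'
#' Closed form: spectral radius \eqn{r = 2w} (eigenvalues
#' \eqn{2w\cos(2\pi k/n)}), uniform dominant eigenvector, variance 0.
#'
#' @param n Node count (>= 3).
#' @param w Common weight (> 0).
#' @return A [WeightedNetwork-class].
#' @examples
#' spectralRadius(ringUniform(6, 10))  # 20
#' @export
ringUniform <- function(n, w) {
  stopifnot(n >= 3, w > 0)
  A <- matrix(0, n, n)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  A[idx] <- w
  A[idx[, c(2, 1)]] <- w
  weightedNetwork(A)
}

#' Star network with uniform weights
#'
#' Node 1 is the hub, nodes 2..n are leaves. Closed form: spectral radius
#' \eqn{r = w\sqrt{n-1}}; under unit Euclidean norm the hub score is
#' \eqn{\sqrt{1/2}} and each leaf score \eqn{\sqrt{1/(2(n-1))}}.
#'
#' @param n Node count (>= 3).
#' @param w Common weight (> 0).
#' @return A [WeightedNetwork-class].
#' @examples
#' spectralRadius(starUniform(5, 1))  # 2
#' @export
starUniform <- function(n, w) {
  stopifnot(n >= 3, w > 0)
  A <- matrix(0, n, n)
  A[1, 2:n] <- w
  A[2:n, 1] <- w
  weightedNetwork(A)
}

#' Random conforming network
#'
#' Draws the free weights (connected upper-triangle pairs of the pattern)
#' i.i.d. uniform on \eqn{[w_{min}, w_{max}]} and expands them into a
#' symmetric, zero-diagonal network. Deterministic for a given seed; the
#' caller's RNG state is left untouched.
#'
#' @param n Node count.
#' @param wMin,wMax Weight box (0 < wMin <= wMax).
#' @param seed RNG seed.
#' @param pattern Optional [StructurePattern-class] (defaults to fully
#'   connected symmetric). A pattern that disconnects the graph is rejected.
#' @return A [WeightedNetwork-class].
#' @examples
#' net <- randomConforming(6, 1, 50, seed = 1)
#' @export
randomConforming <- function(n, wMin = 1, wMax = 50, seed = 1L,
                             pattern = NULL) {
  stopifnot(wMin > 0, wMin <= wMax)
  if (is.null(pattern)) pattern <- structurePattern(n)
  stopifnot(pattern@n == n)
  fp <- freeParameterization(pattern)
  ## connectivity of the pattern itself (all free pairs present)
  mask <- matrix(0, n, n)
  mask[cbind(fp$iu, fp$ju)] <- 1
  mask[cbind(fp$ju, fp$iu)] <- 1
  if (!.isConnectedMatrix(mask))
    stop("pattern disconnects the graph: no connected network can conform",
         call. = FALSE)
  theta <- .withSeed(seed, runif(fp$nFree, wMin, wMax))
  expandFreeWeights(theta, pattern)
}

## evaluate expr under set.seed(seed), restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
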