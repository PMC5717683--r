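# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: power iteration instead of the dense
# eigensolver, direct moment sums instead of the expanded skewness formula.

## dominant eigenvalue of a symmetric nonnegative matrix by power iteration
powerIterationRadius <- function(A, iter = 10000, tol = 1e-14) {
  x <- rep(1 / sqrt(nrow(A)), nrow(A))
  r <- 0
  for (k in seq_len(iter)) {
    y <- A %*% x
    rNew <- sqrt(sum(y^2))
    x <- as.vector(y) / rNew
    if (abs(rNew - r) < tol * max(1, rNew)) break
    r <- rNew
  }
  sum(x * (A %*% x))  # Rayleigh quotient
}

## population moments straight from their definitions
directVariance <- function(x) sum((x - mean(x))^2) / length(x)
directSkewness <- function(x) {
  v <- directVariance(x)
  (sum((x - mean(x))^3) / length(x)) / v^1.5
}

## random symmetric zero-diagonal nonnegative matrix (plain base R)
randomSymmetricMatrix <- function(n, wMin = 1, wMax = 50) {
  A <- matrix(0, n, n)
  w <- runif(n * (n - 1) / 2, wMin, wMax)
  A[upper.tri(A)] <- w
  A <- A + t(A)
  A
}

## random positive unit-Euclidean-norm vector
randomUnitVector <- function(n) {
  x <- abs(rnorm(n)) + 1e-6
  x / sqrt(sum(x^2))
}
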