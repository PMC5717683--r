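# Spectral radius, dominant eigenvector, and the eigenvector moments.

test_that("spectral radius matches closed forms and the power-iteration oracle", {
  # 2-node single edge: eigenvalues +/- w
  expect_equal(spectralRadius(weightedNetwork(matrix(c(0, 7, 7, 0), 2))), 7)
  # complete uniform: (n-1) w
  expect_equal(spectralRadius(completeUniform(6, 16)), 80, tolerance = 1e-12)
  # random symmetric matrices vs an independently written power iteration
  set.seed(11)
  for (k in 1:10) {
    A <- randomSymmetricMatrix(5)
    expect_equal(spectralRadius(A), powerIterationRadius(A),
                 tolerance = 1e-10)
  }
})

test_that("spectral radius rejects malformed input", {
  expect_error(spectralRadius(matrix(1:6, 2, 3)), "square")
  A <- matrix(c(0, NA, NA, 0), 2)
  expect_error(spectralRadius(A), "NA")
})

test_that("dominant eigenvector is the unit-norm nonnegative Perron vector", {
  # complete uniform network: all elements 1/sqrt(n)
  x <- dominantEigenvector(completeUniform(7, 3))
  expect_equal(x, rep(1 / sqrt(7), 7), tolerance = 1e-12)
  # star: hub strictly above the (equal) leaves
  xs <- dominantEigenvector(starUniform(5, 2))
  expect_gt(xs[1], max(xs[-1]))
  expect_equal(max(xs[-1]) - min(xs[-1]), 0, tolerance = 1e-12)
  # eigen-residual on random matrices: A x = r x
  set.seed(12)
  for (k in 1:10) {
    A <- randomSymmetricMatrix(6)
    r <- spectralRadius(A)
    x <- dominantEigenvector(A)
    expect_equal(sum(x^2), 1, tolerance = 1e-12)
    expect_true(all(x >= 0))
    expect_lt(sqrt(sum((A %*% x - r * x)^2)), 1e-10 * r)
  }
})

test_that("dominant eigenvector requires a connected (irreducible) matrix", {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 5
  A[3, 4] <- A[4, 3] <- 3
  expect_error(dominantEigenvector(A), "disconnected")
})

test_that("eigenvector variance is the population variance", {
  expect_equal(eigvecVariance(rep(0.3, 9)), 0)
  expect_equal(eigvecVariance(c(1, 0, 0, 0)), 3 / 16)
  expect_error(eigvecVariance(numeric(0)), "empty")
  set.seed(13)
  for (k in 1:50) {
    x <- rnorm(sample(3:30, 1))
    expect_equal(eigvecVariance(x), directVariance(x), tolerance = 1e-12)
  }
})

test_that("eigenvector skewness matches the direct third-moment oracle", {
  # symmetric two-point distribution has zero skewness
  expect_equal(eigvecSkewness(c(0.2, 0.2, 0.7, 0.7)), 0, tolerance = 1e-12)
  # extremal two-point closed form: (n-2)/sqrt(n-1)
  expect_equal(eigvecSkewness(c(1, 0, 0, 0, 0)), 3 / 2, tolerance = 1e-12)
  expect_error(eigvecSkewness(rep(1 / 2, 4)), "homogeneous")
  set.seed(14)
  for (k in 1:50) {
    x <- rnorm(sample(3:30, 1))
    expect_equal(eigvecSkewness(x), directSkewness(x), tolerance = 1e-10)
  }
})

test_that("the expanded skewness formula equals the central-moment form", {
  # the implementation expands (1/n) sum x^3 - 3 m v - m^3 over v^{3/2};
  # check the algebraic identity on a large batch of random vectors
  set.seed(15)
  for (k in 1:1000) {
    x <- randomUnitVector(sample(3:20, 1))
    expect_equal(eigvecSkewness(x), directSkewness(x), tolerance = 1e-9)
  }
})

test_that("skewness of positive unit vectors respects the extremal bound", {
  set.seed(16)
  for (k in 1:1000) {
    n <- sample(3:20, 1)
    x <- randomUnitVector(n)
    expect_lte(abs(eigvecSkewness(x)), (n - 2) / sqrt(n - 1) + 1e-9)
  }
})

test_that("spectralSummary bundles consistent metrics", {
  s <- spectralSummary(completeUniform(6, 16))
  expect_equal(spectralRadius(s), 80, tolerance = 1e-10)
  expect_equal(eigvecVariance(s), 0, tolerance = 1e-12)
  expect_true(is.na(eigvecSkewness(s)))
  # eigen-residual contract for summaries of connected nets
  set.seed(17)
  A <- randomSymmetricMatrix(8)
  s2 <- spectralSummary(weightedNetwork(A))
  expect_lt(sqrt(sum((A %*% dominantEigenvector(s2) -
                        spectralRadius(s2) * dominantEigenvector(s2))^2)),
            1e-8 * spectralRadius(s2))
})

test_that("metrics are permutation invariant and scale covariant", {
  set.seed(18)
  for (k in 1:10) {
    A <- randomSymmetricMatrix(7)
    s0 <- spectralSummary(weightedNetwork(A))
    # relabeling nodes changes nothing
    p <- sample(7)
    s1 <- spectralSummary(weightedNetwork(A[p, p]))
    expect_equal(spectralRadius(s1), spectralRadius(s0), tolerance = 1e-10)
    expect_equal(eigvecVariance(s1), eigvecVariance(s0), tolerance = 1e-10)
    expect_equal(eigvecSkewness(s1), eigvecSkewness(s0), tolerance = 1e-10)
    # scaling all weights by c > 0 scales r and leaves the eigenvector alone
    cc <- runif(1, 0.1, 10)
    s2 <- spectralSummary(weightedNetwork(cc * A))
    expect_equal(spectralRadius(s2), cc * spectralRadius(s0),
                 tolerance = 1e-10)
    expect_equal(eigvecVariance(s2), eigvecVariance(s0), tolerance = 1e-10)
    expect_equal(eigvecSkewness(s2), eigvecSkewness(s0), tolerance = 1e-10)
  }
})

test_that("network invariants are enforced at construction", {
  expect_error(weightedNetwork(matrix(c(1, 2, 2, 0), 2)), "diagonal")
  expect_error(weightedNetwork(matrix(c(0, -1, -1, 0), 2)), ">= 0")
  expect_error(weightedNetwork(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  # pattern zeros must hold
  pat <- structurePattern(3, disconnected = rbind(c(1, 2)))
  A <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
  expect_error(new("WeightedNetwork", weights = A, pattern = pat),
               "disconnected")
})
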