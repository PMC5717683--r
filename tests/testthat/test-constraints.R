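# The equality-constraint system B a = E and the free parameterization.

test_that("system for a fully connected symmetric pattern has the right rows", {
  sys <- buildEqualitySystem(structurePattern(3))
  kinds <- table(rowKinds(sys))
  expect_equal(unname(kinds[["diagonal"]]), 3)
  expect_equal(unname(kinds[["symmetry"]]), 3)
  expect_equal(unname(kinds[["empty"]]), 3)
  # any symmetric zero-diagonal 3x3 matrix satisfies the system exactly
  set.seed(21)
  for (k in 1:20) {
    A <- randomSymmetricMatrix(3)
    expect_true(satisfiesConstraints(sys, A, tol = 0))
  }
})

test_that("disconnection pairs produce two zero-forcing rows", {
  pat <- structurePattern(3, disconnected = rbind(c(1, 2)))
  sys <- buildEqualitySystem(pat)
  kinds <- table(rowKinds(sys))
  expect_equal(unname(kinds[["disconnection"]]), 2)
  expect_equal(unname(kinds[["symmetry"]]), 2)  # remaining connected pairs
  A <- matrix(c(0, 0, 2, 0, 0, 3, 2, 3, 0), 3)
  expect_true(satisfiesConstraints(sys, A, tol = 0))
  A[1, 2] <- A[2, 1] <- 1  # violates the forced zero
  expect_false(satisfiesConstraints(sys, A, tol = 1e-9))
})

test_that("the zero matrix satisfies every system", {
  for (n in c(3, 5, 8)) {
    sys <- buildEqualitySystem(
      structurePattern(n, disconnected = rbind(c(1, 2))))
    expect_true(satisfiesConstraints(sys, matrix(0, n, n), tol = 0))
  }
})

test_that("satisfiesConstraints flags violations and dimension mismatches", {
  sys <- buildEqualitySystem(structurePattern(4))
  set.seed(22)
  A <- randomSymmetricMatrix(4)
  expect_true(satisfiesConstraints(sys, A))
  B <- A; B[2, 2] <- 1                 # nonzero diagonal
  expect_false(satisfiesConstraints(sys, B))
  C <- A; C[1, 2] <- C[1, 2] + 0.5     # asymmetric
  expect_false(satisfiesConstraints(sys, C))
  expect_error(satisfiesConstraints(sys, matrix(0, 5, 5)), "mismatch")
})

test_that("free parameterization counts and round-trips", {
  expect_equal(freeParameterization(structurePattern(6))$nFree, 15)
  expect_equal(freeParameterization(structurePattern(10))$nFree, 45)
  pat <- structurePattern(6, disconnected = rbind(c(1, 2), c(3, 4)))
  expect_equal(freeParameterization(pat)$nFree, 13)
  # expand . reduce = identity on random conforming matrices
  set.seed(23)
  for (k in 1:100) {
    theta <- runif(13, 1, 50)
    net <- expandFreeWeights(theta, pat)
    expect_identical(reduceToFreeWeights(net), theta)
  }
})

test_that("expanded free weights always satisfy the constraints exactly", {
  pats <- list(structurePattern(4),
               structurePattern(6, disconnected = rbind(c(2, 5))),
               structurePattern(8, disconnected = rbind(c(1, 8), c(2, 3))))
  set.seed(24)
  for (pat in pats) {
    sys <- buildEqualitySystem(pat)
    fp <- freeParameterization(pat)
    expect_equal(unname(table(rowKinds(sys))[["symmetry"]]), fp$nFree)
    for (k in 1:20) {
      net <- expandFreeWeights(runif(fp$nFree, 0.1, 100), pat)
      expect_true(satisfiesConstraints(sys, net, tol = 1e-12))
    }
  }
})

test_that("pattern validation rejects malformed pairs", {
  expect_error(structurePattern(3, disconnected = rbind(c(2, 2))),
               "cannot be marked")
  expect_error(structurePattern(3, disconnected = rbind(c(1, 4))),
               "outside")
})
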