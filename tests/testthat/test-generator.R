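# The constrained-minimisation + hill-climb generator.

critFor <- function(summ, n, seed = 1L, ...) {
  generationCriteria(n, rStar = spectralRadius(summ),
                     vStar = eigvecVariance(summ),
                     sStar = eigvecSkewness(summ), seed = seed, ...)
}

test_that("random initial matrices respect bounds, symmetry and the seed", {
  crit <- generationCriteria(6, 80, 0.026, seed = 5L)
  set.seed(5)
  net <- randomInitialMatrix(crit)
  w <- reduceToFreeWeights(net)
  expect_length(w, 15)
  expect_true(all(w >= 1 & w <= 50))
  expect_identical(adjacency(net), t(adjacency(net)))
  set.seed(5)
  expect_identical(adjacency(randomInitialMatrix(crit)), adjacency(net))
})

test_that("initial weights are uniform on the box", {
  crit <- generationCriteria(6, 80, 0.026, wMin = 1, wMax = 50)
  set.seed(31)
  w <- replicate(100, reduceToFreeWeights(randomInitialMatrix(crit)))
  m <- mean(w)  # 1500 draws
  se <- (50 - 1) / sqrt(12) / sqrt(length(w))
  expect_lt(abs(m - (1 + 50) / 2), 3 * se)
})

test_that("objective recomposes from the summary and has closed-form cases", {
  # exact match => 0
  net <- randomConforming(6, 1, 50, seed = 32)
  crit0 <- critFor(spectralSummary(net), 6)
  expect_equal(objectiveValue(net, crit0), 0, tolerance = 1e-12)
  # omega = (1,0,0) reduces to (r* - r0)^2: uniform K6 w=16, r*=90 -> 100
  crit1 <- generationCriteria(6, 90, 0, omega = c(1, 0, 0))
  expect_equal(objectiveValue(completeUniform(6, 16), crit1), 100,
               tolerance = 1e-9)
  # random criteria: matches independent recomposition
  set.seed(33)
  for (k in 1:10) {
    net <- randomConforming(5, 1, 50, seed = 100 + k)
    s <- spectralSummary(net)
    crit <- generationCriteria(5, runif(1, 10, 90), runif(1, 0.001, 0.05),
                               runif(1, -1, 1))
    direct <- crit@omega[1] * (crit@rStar - spectralRadius(s))^2 +
      crit@omega[2] * (crit@vStar - eigvecVariance(s))^2 +
      crit@omega[3] * (crit@sStar - eigvecSkewness(s))^2
    expect_equal(objectiveValue(net, crit), direct, tolerance = 1e-12)
  }
})

test_that("objective errors when skewness is active but undefined", {
  crit <- generationCriteria(6, 80, 0, sStar = 0.5)
  expect_error(objectiveValue(completeUniform(6, 16), crit), "homogeneous")
})

test_that("minimizeStep is monotone and keeps matrices conforming", {
  crit <- generationCriteria(6, 65, 0.0086, sStar = 1.086, seed = 1L)
  sys <- buildEqualitySystem(networkPattern(crit))
  set.seed(34)
  for (k in 1:15) {
    start <- randomInitialMatrix(crit)
    out <- minimizeStep(start, crit)
    expect_lte(objectiveValue(out, crit),
               objectiveValue(start, crit) + 1e-9)
    expect_true(satisfiesConstraints(sys, out, tol = 1e-9))
    w <- reduceToFreeWeights(out)
    expect_true(all(w >= crit@wFloor & w <= crit@wMax))
  }
})

test_that("minimizeStep leaves an already-optimal start at the optimum", {
  net <- randomConforming(8, 1, 50, seed = 35)
  crit <- critFor(spectralSummary(net), 8)
  out <- minimizeStep(net, crit)
  expect_lte(objectiveValue(out, crit), 1e-9)
})

test_that("a pure spectral-radius criterion always admits descent", {
  # scale covariance guarantees a descent direction for omega = (1,0,0)
  set.seed(36)
  for (k in 1:5) {
    start <- randomConforming(6, 1, 40, seed = 200 + k)
    r0 <- spectralRadius(start)
    crit <- generationCriteria(6, 1.15 * r0, 0, omega = c(1, 0, 0))
    out <- minimizeStep(start, crit)
    expect_lt(objectiveValue(out, crit), objectiveValue(start, crit))
  }
})

test_that("perturbation redraws exactly one symmetric pair within bounds", {
  crit <- generationCriteria(6, 80, 0.026)
  net <- randomConforming(6, 1, 50, seed = 37)
  set.seed(37)
  for (k in 1:20) {
    pert <- perturbNetwork(net, crit)
    d <- which(adjacency(pert) != adjacency(net))
    expect_length(d, 2)  # (i,j) and (j,i)
    expect_identical(adjacency(pert), t(adjacency(pert)))
    expect_true(all(diag(adjacency(pert)) == 0))
    wNew <- adjacency(pert)[d[1]]
    expect_true(wNew >= 1 && wNew <= 50)
  }
})

test_that("perturbation selects pairs uniformly", {
  crit <- generationCriteria(6, 80, 0.026)
  net <- completeUniform(6, 100)  # weights outside [1,50]: every redraw differs
  set.seed(38)
  nrep <- 6000
  hits <- integer(15)
  fp <- freeParameterization(networkPattern(net))
  key <- paste(fp$iu, fp$ju)
  for (k in seq_len(nrep)) {
    pert <- perturbNetwork(net, crit)
    d <- which(adjacency(pert) != adjacency(net), arr.ind = TRUE)
    ij <- d[d[, 1] < d[, 2], , drop = FALSE]
    hits[match(paste(ij[1], ij[2]), key)] <- hits[match(paste(ij[1], ij[2]), key)] + 1L
  }
  p <- 1 / 15
  se <- sqrt(p * (1 - p) * nrep)
  expect_true(all(abs(hits - nrep * p) <= 3.5 * se))
})

test_that("metric differences use relative mode with absolute fallback", {
  net <- randomConforming(6, 1, 50, seed = 39)
  s <- spectralSummary(net)
  crit <- critFor(s, 6)
  expect_equal(unname(metricDifferences(s, crit)), c(0, 0, 0))
  crit2 <- generationCriteria(6, 20, 0.02, sStar = 0)
  s2 <- new("SpectralSummary", r = 21, eigenvector = dominantEigenvector(s),
            mean = s@mean, v = 0.02, s = 0.02)
  d <- metricDifferences(s2, crit2)
  expect_equal(unname(d[["dr"]]), 0.05)   # relative: |20-21|/20
  expect_equal(unname(d[["ds"]]), 0.02)   # absolute fallback at target 0
})

test_that("generation from its own metrics converges immediately", {
  M <- randomConforming(8, 1, 50, seed = 40)
  crit <- critFor(spectralSummary(M), 8)
  res <- generateNetwork(crit, initial = M)
  expect_true(converged(res))
  expect_identical(outerIterations(res), 0L)
})

test_that("parameter recovery: criteria measured from one network are met from a fresh start", {
  M <- randomConforming(7, 1, 50, seed = 41)
  s <- spectralSummary(M)
  crit <- critFor(s, 7, seed = 1L)
  res <- generateNetwork(crit)
  expect_true(converged(res))
  d <- metricDifferences(achievedMetrics(res), crit)
  expect_true(all(d <= c(0.01, 0.01, 0.01)))
})

test_that("infeasible criteria are rejected before any work", {
  # n=6: extremal skewness bound is 4/sqrt(5) ~ 1.789
  crit <- generationCriteria(6, 80, 0.02, sStar = 3.0)
  expect_error(generateNetwork(crit), "extremal bound")
  # skewness requested with v* = 0
  crit2 <- generationCriteria(6, 80, 0, sStar = 1)
  expect_error(generateNetwork(crit2), "v\\* = 0")
})

test_that("generation is deterministic in (seed, criteria)", {
  crit <- generationCriteria(6, 65, 0.0086, sStar = 1.086, seed = 7L)
  r1 <- generateNetwork(crit)
  r2 <- generateNetwork(crit)
  expect_identical(adjacency(finalNetwork(r1)), adjacency(finalNetwork(r2)))
  expect_identical(trajectory(r1), trajectory(r2))
  expect_identical(outerIterations(r1), outerIterations(r2))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(generateNetwork(generationCriteria(6, 80, 0.026, seed = 2L)))
  expect_identical(runif(3), before)
})

test_that("emitted networks satisfy constraints and respect the weight cap", {
  crit <- generationCriteria(6, 60, 0.01, sStar = -0.5, seed = 3L,
                             maxOuter = 50L)
  res <- generateNetwork(crit)
  sys <- buildEqualitySystem(networkPattern(crit))
  expect_true(satisfiesConstraints(sys, finalNetwork(res), tol = 1e-9))
  w <- reduceToFreeWeights(finalNetwork(res))
  expect_true(all(w > 0 & w <= crit@wMax))
})

test_that("generation under a disconnection pattern keeps the forced zeros", {
  pat <- structurePattern(6, disconnected = rbind(c(1, 2)))
  crit <- generationCriteria(6, 60, 0.01, seed = 4L, pattern = pat)
  res <- generateNetwork(crit)
  A <- adjacency(finalNetwork(res))
  expect_identical(A[1, 2], 0)
  expect_identical(A[2, 1], 0)
  expect_true(converged(res))
})
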