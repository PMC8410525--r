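test_that("Gaussian kernel and random walk match closed forms", {
  # two identical points: zero distance forces kernel 1 everywhere
  am <- buildAffinity(matrix(c(1, 2, 1, 2), 2, 2, byrow = TRUE),
                      kernelScale = "fixed", epsilon = 3)
  expect_equal(am@similarity, matrix(1, 2, 2))
  expect_equal(am@randomWalk[1, ], c(0.5, 0.5))

  # points {0, 1} in 1-D with eps = 1: off-diagonal kernel is exp(-1)
  am <- buildAffinity(matrix(c(0, 1), ncol = 1),
                      kernelScale = "fixed", epsilon = 1)
  expect_equal(am@similarity[1, 2], exp(-1))

  # median bandwidth equals the median of all pairwise squared distances,
  # computed by a brute-force double loop
  set.seed(7)
  x <- matrix(rnorm(10), 5, 2)
  d2 <- c()
  for (i in 1:4) for (j in (i + 1):5) d2 <- c(d2, sum((x[i, ] - x[j, ])^2))
  am <- buildAffinity(x, kernelScale = "median")
  expect_equal(am@kernelScale, median(d2))
  expect_lt(max(abs(rowSums(am@randomWalk) - 1)), 1e-10)
})

test_that("affinity construction rejects invalid input", {
  expect_error(buildAffinity(matrix(c(0, NA), ncol = 1)), "non-finite")
  expect_error(buildAffinity(matrix(0, 1, 2)), "at least 2")
  expect_error(buildAffinity(matrix(c(0, 1), ncol = 1),
                             kernelScale = "fixed", epsilon = -1), "positive")
})

test_that("embedding matches a dense eigendecomposition oracle", {
  # 3-point chain in 1-D: compare against eigen() on the explicit P
  am <- buildAffinity(matrix(0:2, ncol = 1), kernelScale = "fixed",
                      epsilon = 1)
  em <- diffusionEmbed(am, nComponents = 2, diffusionTime = 1)
  oracleVals <- sort(Re(eigen(am@randomWalk)$values), decreasing = TRUE)
  expect_equal(em@eigenvalues, oracleVals[2:3], tolerance = 1e-10)
  # returned eigenvectors are right eigenvectors of P
  for (j in 1:2)
    expect_lt(max(abs(am@randomWalk %*% em@eigenvectors[, j] -
                        em@eigenvalues[j] * em@eigenvectors[, j])), 1e-10)
})

test_that("the trivial eigenpair has eigenvalue 1 and a constant eigenvector", {
  set.seed(11)
  x <- matrix(rnorm(24), 8, 3)
  am <- buildAffinity(x)
  # the trivial pair is excluded, so the full operator must have an
  # eigenvalue-1 constant-eigenvector pair not present among the returned ones
  es <- eigen(am@randomWalk)
  i <- which.min(abs(es$values - 1))
  expect_equal(Re(es$values[i]), 1, tolerance = 1e-10)
  v <- Re(es$vectors[, i])
  expect_lt(sd(v) / abs(mean(v)), 1e-8)
  em <- diffusionEmbed(am, nComponents = 3)
  expect_true(all(em@eigenvalues < 1))
})

test_that("circle angles are recovered from the two leading coordinates", {
  set.seed(3)
  theta <- sort(runif(200, 0, 2 * pi))
  x <- cbind(cos(theta), sin(theta))
  em <- diffusionEmbed(buildAffinity(x), nComponents = 2)
  angle <- atan2(embCoordinates(em)[, 2], embCoordinates(em)[, 1])
  expect_gte(abs(circularCorrelation(angle, theta)), 0.95)
})

test_that("full-spectrum embedding distance equals the diffusion distance", {
  set.seed(5)
  x <- matrix(rnorm(12), 6, 2)
  am <- buildAffinity(x)
  for (t in 1:3) {
    em <- diffusionEmbed(am, nComponents = 5, diffusionTime = t)
    co <- embCoordinates(em)
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(sqrt(sum((co[i, ] - co[j, ])^2)),
                   diffusionDistance(am, t, i, j), tolerance = 1e-8)
    }
  }
})

test_that("diffusion distance is symmetric, zero at i = j", {
  set.seed(9)
  am <- buildAffinity(matrix(rnorm(14), 7, 2))
  expect_equal(diffusionDistance(am, 2, 3, 3), 0)
  expect_equal(diffusionDistance(am, 2, 1, 5), diffusionDistance(am, 2, 5, 1))
})

test_that("truncated embedding distance is monotone in k and bounded by D_t", {
  set.seed(13)
  am <- buildAffinity(matrix(rnorm(20), 10, 2))
  dfull <- diffusionDistance(am, 1, 2, 7)
  prev <- 0
  for (k in 1:9) {
    co <- embCoordinates(diffusionEmbed(am, nComponents = k))
    dk <- sqrt(sum((co[2, ] - co[7, ])^2))
    expect_gte(dk, prev - 1e-12)
    expect_lte(dk, dfull + 1e-8)
    prev <- dk
  }
})

test_that("permuting input points permutes embedding rows identically", {
  set.seed(17)
  x <- matrix(rnorm(30), 10, 3)
  perm <- sample(10)
  e1 <- diffusionEmbed(buildAffinity(x), 3)
  e2 <- diffusionEmbed(buildAffinity(x[perm, ]), 3)
  expect_equal(embCoordinates(e2), embCoordinates(e1)[perm, ],
               tolerance = 1e-8)
})

test_that("eigenvalues of random instances respect the spectral bound", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:20, 1)
    em <- diffusionEmbed(buildAffinity(matrix(rnorm(n * 3), n, 3)),
                         nComponents = n - 1)
    expect_true(all(abs(em@eigenvalues) <= 1 + 1e-10))
  }
})

test_that("parameter errors are raised for out-of-range requests", {
  am <- buildAffinity(matrix(rnorm(8), 4, 2))
  expect_error(diffusionEmbed(am, nComponents = 4), "n - 1")
  expect_error(diffusionEmbed(am, nComponents = 2, diffusionTime = 0), ">= 1")
  expect_error(diffusionDistance(am, 0, 1, 2), ">= 1")
  expect_error(diffusionDistance(am, 1, 0, 2), "out of range")
})
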