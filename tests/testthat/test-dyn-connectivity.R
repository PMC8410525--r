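# Brute-force evaluation of the windowed MTD definition, term by term.
mtdOracle <- function(x, w) {
  V <- nrow(x); Tn <- ncol(x)
  dx <- matrix(0, V, Tn - 1)
  for (i in 1:V) for (t in 2:Tn) dx[i, t - 1] <- x[i, t] - x[i, t - 1]
  sds <- apply(dx, 1, function(v) sqrt(mean((v - mean(v))^2)))
  nw <- Tn - 1 - w
  out <- array(0, dim = c(V, V, nw))
  for (t in 1:nw) for (i in 1:V) for (j in 1:V) {
    acc <- 0
    for (k in t:(t + w)) acc <- acc + dx[i, k] * dx[j, k]
    out[i, j, t] <- acc / (w * sds[i] * sds[j])
  }
  out
}

# Term-by-term participation coefficient.
pcOracle <- function(w, membership) {
  wp <- pmax(w, 0); diag(wp) <- 0
  sapply(seq_len(nrow(w)), function(i) {
    ki <- sum(wp[i, ])
    if (ki == 0) return(0)
    1 - sum(sapply(unique(membership), function(s)
      (sum(wp[i, membership == s]) / ki)^2))
  })
}

test_that("windowed MTD agrees with the term-by-term oracle", {
  set.seed(1)
  x <- matrix(rnorm(3 * 12), 3, 12)
  dc <- mtd(x, window = 3)
  expect_equal(dc@weights, mtdOracle(x, 3), tolerance = 1e-12)
  expect_equal(dim(dc@weights)[3], 12L - 1L - 3L)
  expect_equal(frameMap(dc), as.integer(2:9))
})

test_that("identical nodes share all MTD edges and slices are symmetric", {
  set.seed(2)
  base <- rnorm(20)
  x <- rbind(base, base, rnorm(20))
  dc <- mtd(x, window = 4)
  expect_equal(dc@weights[1, 3, ], dc@weights[2, 3, ], tolerance = 1e-12)
  expect_equal(dc@weights[1, 1, ], dc@weights[1, 2, ], tolerance = 1e-12)
  for (t in seq_len(dim(dc@weights)[3]))
    expect_lt(max(abs(dc@weights[, , t] - t(dc@weights[, , t]))), 1e-10)
})

test_that("MTD is invariant to positive rescaling of a node", {
  set.seed(3)
  x <- matrix(rnorm(4 * 25), 4, 25)
  x2 <- x; x2[2, ] <- 37.5 * x2[2, ]
  expect_equal(mtd(x, 5)@weights, mtd(x2, 5)@weights, tolerance = 1e-10)
})

test_that("nodes with constant derivative are rejected by name", {
  x <- matrix(rnorm(3 * 15), 3, 15)
  x[2, ] <- seq_len(15)  # linear: zero derivative SD
  rownames(x) <- c("a", "lin", "c")
  expect_error(mtd(x, 3), "lin")
  expect_error(mtd(matrix(rnorm(6), 2, 3), 3), "window \\+ 2")
})

test_that("Louvain separates disconnected cliques and merges uniform graphs", {
  blockA <- matrix(1, 4, 4); diag(blockA) <- 0
  w <- rbind(cbind(blockA, matrix(0, 4, 4)),
             cbind(matrix(0, 4, 4), blockA))
  lab <- detectCommunities(w, seed = 1)
  expect_equal(length(unique(lab)), 2L)
  expect_equal(length(unique(lab[1:4])), 1L)
  expect_equal(length(unique(lab[5:8])), 1L)

  full <- matrix(1, 6, 6); diag(full) <- 0
  expect_equal(length(unique(detectCommunities(full, seed = 1))), 1L)
})

test_that("planted partitions are recovered by Louvain", {
  ari <- sapply(1:10, function(seed) {
    pb <- plantedBlocks(nBlocks = 3, perBlock = 10, pIn = 0.8, pOut = 0.05,
                        seed = seed)
    adjustedRand(detectCommunities(pb$adj, seed = seed), pb$labels)
  })
  expect_gte(median(ari), 0.9)
})

test_that("community detection is deterministic under a fixed seed", {
  set.seed(4)
  w <- matrix(runif(100), 10, 10); w <- (w + t(w)) / 2
  expect_identical(detectCommunities(w, seed = 42),
                   detectCommunities(w, seed = 42))
  w0 <- matrix(0, 4, 4)
  expect_warning(lab <- detectCommunities(w0, seed = 1), "single-module")
  expect_equal(lab, rep(1L, 4))
})

test_that("participation coefficient matches closed forms and the oracle", {
  # all links inside the node's own module
  w <- matrix(1, 4, 4); diag(w) <- 0
  expect_equal(participationCoef(w, rep(1, 4)), rep(0, 4))
  # equal strength to each of 4 modules: 1 - 4 (1/4)^2 = 0.75
  w8 <- matrix(0, 9, 9)
  w8[1, 2:9] <- rep(0.5, 8); w8[2:9, 1] <- 0.5
  m8 <- c(1, rep(1:4, each = 2))
  expect_equal(participationCoef(w8, m8)[1], 0.75)
  # random instance against the term-by-term oracle
  set.seed(5)
  w <- matrix(rnorm(100), 10, 10); w <- (w + t(w)) / 2
  mem <- sample(1:3, 10, replace = TRUE)
  expect_equal(participationCoef(w, mem), pcOracle(w, mem),
               tolerance = 1e-12)
})

test_that("participation respects the 1 - 1/N_M upper bound", {
  set.seed(6)
  for (rep in 1:5) {
    w <- abs(matrix(rnorm(144), 12, 12)); w <- (w + t(w)) / 2
    mem <- sample(1:4, 12, replace = TRUE)
    nm <- length(unique(mem))
    b <- participationCoef(w, mem)
    expect_true(all(b <= 1 - 1 / nm + 1e-12))
    expect_true(all(b >= 0))
  }
})

test_that("group B_T is the elementwise subject mean", {
  set.seed(7)
  mk <- function(seed) {
    x <- matrix(rnorm(6 * 30), 6, 30)
    dc <- mtd(x, 4)
    participationSeries(dc, dynamicCommunities(dc, seed = seed))
  }
  a <- mk(1); b <- mk(2)
  expect_equal(as.numeric(groupBT(list(a))), globalPC(a))
  expect_equal(as.numeric(groupBT(list(a, b))),
               (globalPC(a) + globalPC(b)) / 2)
  expect_equal(as.numeric(groupBT(list(b, a))),
               as.numeric(groupBT(list(a, b))))
  # mismatched frame maps are rejected
  c2 <- mk(3); c2@frameMap <- c2@frameMap + 1L
  expect_error(groupBT(list(a, c2)), "frame map")
})
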