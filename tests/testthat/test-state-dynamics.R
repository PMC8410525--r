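test_that("CH criterion picks the planted number of clusters", {
  hits4 <- sapply(1:10, function(seed) {
    pc <- plantedClusters(4, nPer = 50, d = 3, sep = 8, seed = seed)
    selectK(pc$coords, kRange = 2:10, seed = seed)$k == 4
  })
  expect_gte(sum(hits4), 9)
  pc2 <- plantedClusters(2, nPer = 50, d = 3, sep = 8, seed = 1)
  expect_equal(selectK(pc2$coords, kRange = 2:6, seed = 1)$k, 2L)
  expect_error(selectK(pc2$coords, kRange = 1:3), "at least 2")
})

test_that("CH score is positive for non-degenerate clusterings", {
  set.seed(2)
  co <- matrix(rnorm(60), 30, 2)
  expect_gt(chIndex(co, rep(1:3, 10)), 0)
})

test_that("k-means state models satisfy their contracts", {
  # frames already at k distinct points: zero within-cluster dispersion
  pts <- matrix(c(0, 0, 5, 5, -5, 5), 3, 2, byrow = TRUE)
  co <- pts[rep(1:3, each = 10), ]
  sm <- clusterStates(co, 3, seed = 1)
  expect_equal(sort(unique(stateLabels(sm))), 1:3)
  within <- sum((co - stateCentroids(sm)[stateLabels(sm), ])^2)
  expect_lt(within, 1e-12)

  # duplicating every frame leaves the centroids unchanged
  pcc <- plantedClusters(3, nPer = 20, seed = 3)
  sm1 <- clusterStates(pcc$coords, 3, seed = 5)
  sm2 <- clusterStates(rbind(pcc$coords, pcc$coords), 3, seed = 5)
  ord1 <- order(stateCentroids(sm1)[, 1])
  ord2 <- order(stateCentroids(sm2)[, 1])
  expect_equal(stateCentroids(sm1)[ord1, ], stateCentroids(sm2)[ord2, ],
               tolerance = 1e-8, ignore_attr = TRUE)

  # planted labels recovered
  expect_gte(adjustedRand(stateLabels(sm1), pcc$labels), 0.9)
  expect_error(clusterStates(pts, 5, seed = 1), "distinct")
})

test_that("nearest-frame assignment matches a brute-force scan", {
  pc <- plantedClusters(3, nPer = 15, seed = 4)
  sm <- clusterStates(pc$coords, 3, seed = 1)
  set.seed(5)
  newco <- matrix(rnorm(20 * 3, sd = 6), 20, 3)
  got <- assignByNearestFrame(newco, sm)
  want <- sapply(1:20, function(i) {
    d <- colSums((t(pc$coords) - newco[i, ])^2)
    stateLabels(sm)[which.min(d)]
  })
  expect_equal(got, want)
  # a new frame identical to a reference frame inherits its label
  expect_equal(assignByNearestFrame(pc$coords[7, , drop = FALSE], sm),
               stateLabels(sm)[7])
})

test_that("transition models match closed-form chains", {
  # strict alternation
  tm <- transitionModel(rep(1:2, 25))
  expect_equal(transitionMatrix(tm), matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(stationaryDist(tm), c(0.5, 0.5))
  expect_equal(stateEntropy(tm), c(0, 0))

  # 2-state chain: pi = (b, a) / (a + b)
  a <- 0.3; b <- 0.1
  P <- matrix(c(1 - a, a, b, 1 - b), 2, 2, byrow = TRUE)
  lab <- sampleChain(P, 20000, seed = 6)
  tm <- transitionModel(lab)
  expect_equal(stationaryDist(tm), c(b, a) / (a + b), tolerance = 0.03)
  expect_lt(max(abs(stationaryDist(tm) %*% transitionMatrix(tm) -
                      stationaryDist(tm))), 1e-8)
})

test_that("a known 4-state chain is estimated accurately", {
  P <- matrix(c(0.70, 0.10, 0.10, 0.10,
                0.05, 0.80, 0.10, 0.05,
                0.10, 0.10, 0.70, 0.10,
                0.25, 0.25, 0.25, 0.25), 4, 4, byrow = TRUE)
  lab <- sampleChain(P, 10000, seed = 7)
  tm <- transitionModel(lab)
  expect_lt(max(abs(transitionMatrix(tm) - P)), 0.03)
  # uniform outgoing row has entropy log 4
  expect_equal(stateEntropy(tm)[4], log(4), tolerance = 0.01)
  expect_true(all(stateEntropy(tm) >= 0 & stateEntropy(tm) <= log(4) + 1e-12))
})

test_that("transitions are never counted across run boundaries", {
  lab <- c(1, 1, 2, 2, 1, 1, 2, 2)
  runs <- rep(1:2, each = 4)
  tm <- transitionModel(lab, runs = runs)
  # the 2 -> 1 jump only happens at the run boundary, so it must not appear
  expect_equal(transitionMatrix(tm)[2, 1], 0)
})

test_that("relabeling states permutes the transition model consistently", {
  lab <- sampleChain(matrix(c(0.8, 0.1, 0.1,
                              0.2, 0.6, 0.2,
                              0.3, 0.3, 0.4), 3, 3, byrow = TRUE),
                     3000, seed = 8)
  perm <- c(3L, 1L, 2L)  # new label of old state s is perm[s]
  tm1 <- transitionModel(lab)
  tm2 <- transitionModel(perm[lab])
  inv <- order(perm)
  expect_equal(transitionMatrix(tm2)[perm, perm], transitionMatrix(tm1),
               tolerance = 1e-12)
  expect_equal(stationaryDist(tm2)[perm], stationaryDist(tm1),
               tolerance = 1e-10)
  expect_equal(stateEntropy(tm2)[perm], stateEntropy(tm1), tolerance = 1e-12)
})

test_that("states without outgoing transitions are handled with a warning", {
  lab <- c(1, 1, 2, 2, 3)  # state 3 only appears at the end
  expect_warning(tm <- transitionModel(lab), "communicating")
  expect_equal(sum(stationaryDist(tm)), 1)
  expect_equal(stationaryDist(tm)[3], 0)
})

test_that("dwell chi-squared matches hand arithmetic", {
  expect_equal(dwellChisq(c(5, 5, 5, 5))$statistic, 0)
  r <- dwellChisq(c(10, 0, 0, 0))
  expect_equal(r$statistic, 30)
  expect_equal(r$df, 3)
  expect_error(dwellChisq(c(0, 0)), "zero total")
  expect_error(dwellChisq(7), "at least 2")
})

test_that("block trajectories average repetitions positionwise", {
  # a single repetition: trajectory equals its frames
  co <- matrix(seq_len(12), 6, 2)
  design <- data.frame(frame = 1:6, task = "t", block = "b",
                       position = 0:5, run = 1)
  tr <- blockTrajectories(co, design)
  expect_equal(as.matrix(tr[, c("dim1", "dim2")]), co, ignore_attr = TRUE)

  # two repetitions mirrored about the origin average to zero
  co2 <- rbind(co, -co)
  design2 <- data.frame(frame = 1:12, task = "t", block = "b",
                        position = rep(0:5, 2), run = 1)
  tr2 <- blockTrajectories(co2, design2)
  expect_lt(max(abs(as.matrix(tr2[, c("dim1", "dim2")]))), 1e-12)

  # cue frames excluded; unequal repetition lengths rejected by name
  design3 <- data.frame(frame = 1:12, task = "t",
                        block = rep(c("cue", "b"), each = 6),
                        position = rep(0:5, 2), run = 1)
  expect_false("cue" %in% blockTrajectories(co2, design3)$block)
  design4 <- data.frame(frame = 1:12, task = "t", block = "odd",
                        position = c(0:4, 0:6), run = 1)
  expect_error(blockTrajectories(co2, design4), "odd")
})

test_that("noisy repetitions of an arc average toward the true arc", {
  set.seed(9)
  reps <- 25; len <- 20
  arc <- cbind(sin(seq(0, pi, length.out = len)),
               cos(seq(0, pi, length.out = len)))
  co <- do.call(rbind, replicate(reps, arc + matrix(rnorm(len * 2, sd = 0.5),
                                                    len, 2), simplify = FALSE))
  design <- data.frame(frame = seq_len(reps * len), task = "t", block = "b",
                       position = rep(0:(len - 1), reps), run = 1)
  tr <- blockTrajectories(co, design)
  rmse <- sqrt(mean((as.matrix(tr[, c("dim1", "dim2")]) - arc)^2))
  expect_lt(rmse, 2 * 0.5 / sqrt(reps))
})

test_that("projection correlation behaves like a Pearson correlation", {
  set.seed(10)
  co <- matrix(rnorm(200), 100, 2)
  z <- c(1, 1) / sqrt(2)
  proj <- drop(co %*% z)
  expect_equal(projectAndCorrelate(co, proj, z)$r, 1)
  expect_equal(projectAndCorrelate(co, proj, -z)$r, -1)
  big <- matrix(rnorm(20000), 10000, 2)
  r <- projectAndCorrelate(big, rnorm(10000))$r
  expect_lt(abs(r), 0.05)
  expect_error(projectAndCorrelate(co, rep(1, 100)), "undefined")
})

test_that("a planted-state tensor round-trips through the full pipeline", {
  hits <- 0L
  checked <- FALSE
  for (seed in 1:5) {
    sim <- simulateGroupTensor(M = 8, V = 30, T = 1000,
                               latentKind = "markov_states", nStates = 4,
                               seed = seed)
    emb <- twoStepDM(sim$tensor, d1 = 7, d2 = 3)
    sel <- selectK(embCoordinates(emb), kRange = 2:6, seed = 1, nStart = 20)
    if (sel$k != 4L) next
    hits <- hits + 1L
    if (!checked) {
      checked <- TRUE
      expect_gte(adjustedRand(stateLabels(sel$model),
                              sim$truth$stateLabels), 0.9)
      # relabel the estimate to the planted states via the confusion matrix
      tab <- table(stateLabels(sel$model), sim$truth$stateLabels)
      map <- apply(tab, 1, which.max)
      tm <- transitionModel(map[stateLabels(sel$model)])
      truthTm <- transitionModel(sim$truth$stateLabels)
      expect_lt(max(abs(transitionMatrix(tm) - transitionMatrix(truthTm))),
                0.05)
    }
  }
  expect_gte(hits, 4L)
})
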