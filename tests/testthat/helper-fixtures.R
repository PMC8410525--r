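# Shared fixtures built in code at test time.

# n points per cluster around k well-separated centers in d dimensions.
plantedClusters <- function(k, nPer, d = 3, sep = 8, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k, d)
  centers <- centers / sqrt(rowSums(centers^2)) * sep * sd
  # spread centers apart: scale until min pairwise distance >= sep * sd
  repeat {
    dmin <- min(dist(centers))
    if (dmin >= sep * sd) break
    centers <- centers * 1.5
  }
  labels <- rep(seq_len(k), each = nPer)
  coords <- centers[labels, , drop = FALSE] +
    matrix(rnorm(k * nPer * d, sd = sd), k * nPer, d)
  list(coords = coords, labels = labels, centers = centers)
}

# Symmetric planted-partition (stochastic block model) adjacency matrix.
plantedBlocks <- function(nBlocks = 3, perBlock = 10, pIn = 0.8, pOut = 0.05,
                          seed = 1) {
  set.seed(seed)
  n <- nBlocks * perBlock
  labels <- rep(seq_len(nBlocks), each = perBlock)
  p <- ifelse(outer(labels, labels, "=="), pIn, pOut)
  a <- matrix(runif(n * n) < p, n, n) * 1
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  diag(a) <- 0
  list(adj = a, labels = labels)
}

# Sample a label sequence from a known Markov chain.
sampleChain <- function(P, n, seed = 1) {
  set.seed(seed)
  k <- nrow(P)
  s <- integer(n)
  s[1] <- sample.int(k, 1)
  for (t in 2:n) s[t] <- sample.int(k, 1, prob = P[s[t - 1], ])
  s
}
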