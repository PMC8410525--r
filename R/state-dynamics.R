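#' Calinski-Harabasz index of a clustering
#'
#' Ratio of between-cluster to within-cluster dispersion, each scaled by its
#' degrees of freedom: CH = (B / (k - 1)) / (W / (n - k)). Larger is better.
#'
#' @param coords n x d coordinates.
#' @param labels cluster assignment per row.
#' @return the CH score (positive for any non-degenerate clustering).
#' @export
chIndex <- function(coords, labels) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  ks <- unique(labels)
  k <- length(ks)
  if (k < 2L || k >= n) stop("need 2 <= k < n clusters")
  gm <- colMeans(coords)
  B <- 0; W <- 0
  for (s in ks) {
    xs <- coords[labels == s, , drop = FALSE]
    cs <- colMeans(xs)
    B <- B + nrow(xs) * sum((cs - gm)^2)
    W <- W + sum(sweep(xs, 2, cs)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Select the number of brain states by the Calinski-Harabasz criterion
#'
#' Runs seeded k-means (with `nStart` restarts) for every k in `kRange`,
#' scores each clustering with [chIndex()] and returns the k with the largest
#' score. Default range 2..10.
#'
#' @param coords T x d embedding coordinates.
#' @param kRange candidate cluster numbers (all >= 2, < T).
#' @param seed RNG seed.
#' @param nStart k-means restarts per k.
#' @return list with `k` (the argmax), `chScores` (named numeric) and
#'   `models` (the [StateModel-class] for the selected k).
#' @export
selectK <- function(coords, kRange = 2:10, seed = 1L, nStart = 50L) {
  coords <- as.matrix(coords)
  kRange <- as.integer(kRange)
  if (any(kRange < 2L)) stop("k must be at least 2")
  if (any(kRange > nrow(coords) - 1L)) stop("k must be smaller than T")
  scores <- numeric(length(kRange))
  names(scores) <- kRange
  fits <- vector("list", length(kRange))
  for (i in seq_along(kRange)) {
    fits[[i]] <- clusterStates(coords, kRange[i], seed = seed,
                               nStart = nStart)
    scores[i] <- chIndex(coords, stateLabels(fits[[i]]))
  }
  best <- which.max(scores)
  model <- fits[[best]]
  model@chScores <- scores
  list(k = kRange[best], chScores = scores, model = model)
}

#' Cluster embedding frames into discrete brain states
#'
#' Seeded k-means (multiple restarts) on embedding coordinates; frames
#' sharing similar low-dimensional activity geometry are grouped into k
#' recurring states.
#'
#' @param coords T x d embedding coordinates.
#' @param k number of states (>= 2, at most the number of distinct frames).
#' @param seed RNG seed.
#' @param nStart k-means restarts.
#' @return a [StateModel-class].
#' @export
clusterStates <- function(coords, k, seed = 1L, nStart = 50L) {
  coords <- as.matrix(coords)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (nrow(unique(coords)) < k)
    stop("k exceeds the number of distinct frames")
  set.seed(as.integer(seed))
  km <- stats::kmeans(coords, centers = k, nstart = nStart, iter.max = 100L)
  ch <- chIndex(coords, km$cluster)
  names(ch) <- k
  new("StateModel",
      k = k,
      labels = as.integer(km$cluster),
      centroids = km$centers,
      chScores = ch,
      seed = as.integer(seed),
      coords = coords)
}

#' Assign new frames to states by their nearest reference frame
#'
#' Each new frame inherits the state label of the Euclidean-nearest frame in
#' the reference model's coordinates (not the nearest centroid); ties are
#' broken by the lowest reference frame index.
#'
#' @param newCoords T' x d matrix of extended coordinates.
#' @param reference a [StateModel-class].
#' @return integer state labels for the new frames.
#' @export
assignByNearestFrame <- function(newCoords, reference) {
  stopifnot(is(reference, "StateModel"))
  newCoords <- as.matrix(newCoords)
  refc <- reference@coords
  if (nrow(refc) == 0L) stop("invalid input: empty reference")
  if (ncol(newCoords) != ncol(refc))
    stop("invalid input: dimensionality mismatch")
  d2 <- crossSqDist(newCoords, refc)
  nearest <- apply(d2, 1, which.min)  # which.min takes the first (lowest) tie
  reference@labels[nearest]
}

#' Markov transition model of a state sequence
#'
#' Counts transitions between temporally adjacent frames' states
#' (self-transitions included), never across run/task boundaries, and
#' row-normalizes into a stochastic matrix. The stationary distribution is
#' the left eigenvector for eigenvalue 1 (normalized to sum one) and serves
#' as the dwell-time distribution; per-state entropy of the outgoing row,
#' S_i = -sum_j P_ij log P_ij (natural log, 0 log 0 = 0), measures how
#' unpredictable transitions out of each state are.
#'
#' States with fewer than `minTransitions` observed outgoing transitions are
#' listed in `unreliableStates` (their entropy estimates rest on few counts);
#' a state with no outgoing transitions at all gets a zero row and the
#' stationary distribution is computed on the remaining communicating part
#' with a warning.
#'
#' @param labels integer state sequence (values in 1..k).
#' @param runs optional run/task id per frame; transitions are only counted
#'   between consecutive frames sharing a run id.
#' @param nStates total number of states k (defaults to max(labels)).
#' @param minTransitions reliability threshold for the entropy flag.
#' @return a [TransitionModel-class].
#' @export
transitionModel <- function(labels, runs = NULL, nStates = max(labels),
                            minTransitions = 10L) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n < 2L) stop("need at least 2 frames")
  k <- as.integer(nStates)
  if (any(labels < 1L | labels > k)) stop("labels must lie in 1..nStates")
  if (is.null(runs)) runs <- rep(1L, n)
  if (length(runs) != n) stop("runs must have one id per frame")

  from <- labels[-n]; to <- labels[-1L]
  keep <- runs[-n] == runs[-1L]
  counts <- matrix(0, k, k)
  if (any(keep)) {
    tb <- table(factor(from[keep], levels = seq_len(k)),
                factor(to[keep], levels = seq_len(k)))
    counts <- matrix(as.numeric(tb), k, k)
  }
  out <- rowSums(counts)
  P <- matrix(0, k, k)
  nz <- out > 0
  P[nz, ] <- counts[nz, , drop = FALSE] / out[nz]

  if (all(!nz)) stop("no transitions observed")
  if (any(!nz)) {
    warning("state(s) ", paste(which(!nz), collapse = ", "),
            " have no outgoing transitions; stationary distribution ",
            "computed on the communicating part")
    sub <- which(nz)
    Psub <- counts[sub, sub, drop = FALSE]
    rs <- rowSums(Psub)
    if (any(rs == 0)) stop("communicating part is degenerate")
    Psub <- Psub / rs
    pis <- .stationaryLeft(Psub)
    pi0 <- rep(0, k); pi0[sub] <- pis
  } else {
    pi0 <- .stationaryLeft(P)
  }
  ent <- apply(P, 1, function(p) { p <- p[p > 0]; -sum(p * log(p)) })
  new("TransitionModel",
      transition = P,
      stationary = pi0,
      entropy = ent,
      dwellCounts = tabulate(labels, nbins = k),
      unreliableStates = as.integer(which(out < minTransitions)))
}

# Left eigenvector of P for eigenvalue 1, as a probability vector.
.stationaryLeft <- function(P) {
  es <- eigen(t(P))
  i <- which.min(abs(es$values - 1))
  v <- Re(es$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Chi-squared test of dwell-time uniformity
#'
#' Pearson chi-squared statistic of per-state dwell counts against the
#' uniform expectation (equal time in every state), df = k - 1. A large
#' statistic indicates the subject concentrated time in particular states.
#'
#' @param counts nonnegative integer dwell counts per state (k >= 2).
#' @return list with `statistic`, `df` and `p.value`.
#' @export
dwellChisq <- function(counts) {
  counts <- as.numeric(counts)
  k <- length(counts)
  if (k < 2L) stop("need at least 2 states")
  if (sum(counts) <= 0) stop("invalid input: zero total count")
  ht <- suppressWarnings(
    stats::chisq.test(counts, p = rep(1 / k, k)))
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p.value = unname(ht$p.value))
}

#' Averaged within-block trajectories through the embedding
#'
#' For every non-excluded block type in the task design, averages the
#' embedding coordinates over repetitions at each within-block position,
#' producing a smoothed representative trajectory per block type in temporal
#' order. Cue and fixation frames are excluded by default. Repetitions of a
#' block type must share their length.
#'
#' @param coords T x d embedding coordinates.
#' @param design task design data.frame with columns `frame`, `task`,
#'   `block`, `position`, `run` (frames 1-based, matching `coords` rows).
#' @param exclude block types dropped from trajectories.
#' @return data.frame with columns `block`, `position` and one column per
#'   embedding dimension, ordered by position within block type.
#' @export
blockTrajectories <- function(coords, design,
                              exclude = c("cue", "fixation")) {
  coords <- as.matrix(coords)
  need <- c("frame", "task", "block", "position", "run")
  if (!all(need %in% names(design)))
    stop("design must have columns ", paste(need, collapse = ", "))
  keep <- !(tolower(design$block) %in% tolower(exclude))
  design <- design[keep, , drop = FALSE]
  out <- NULL
  for (b in unique(design$block)) {
    db <- design[design$block == b, , drop = FALSE]
    # repetitions = contiguous runs of the block; all must share a length
    lens <- tapply(db$position, cumsum(db$position == 0), length)
    if (length(unique(lens)) > 1L)
      stop("invalid design: block type '", b,
           "' has repetitions of unequal length")
    pos <- sort(unique(db$position))
    avg <- t(vapply(pos, function(p)
      colMeans(coords[db$frame[db$position == p], , drop = FALSE]),
      numeric(ncol(coords))))
    colnames(avg) <- sprintf("dim%d", seq_len(ncol(coords)))
    out <- rbind(out, data.frame(block = b, position = pos, avg))
  }
  rownames(out) <- NULL
  out
}

#' Project frames on a direction and correlate with a signal
#'
#' Projects each embedding frame onto a unit direction (by default the unit
#' diagonal of the first two embedding coordinates, the axis along which
#' integration varies in the group embedding) and returns the Pearson
#' correlation of the scalar projection with an external per-frame signal
#' such as the group participation coefficient B_T.
#'
#' @param coords T x d embedding coordinates.
#' @param signal length-T numeric signal aligned to the frames.
#' @param direction unit vector of length d; NULL for the default diagonal.
#' @return list with `r` (Pearson correlation) and `projection`.
#' @export
projectAndCorrelate <- function(coords, signal, direction = NULL) {
  coords <- as.matrix(coords)
  if (!all(is.finite(signal))) stop("invalid input: non-finite signal")
  if (length(signal) != nrow(coords))
    stop("signal length must match the number of frames")
  if (is.null(direction)) {
    direction <- rep(0, ncol(coords))
    direction[seq_len(min(2L, ncol(coords)))] <- 1
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be nonzero")
  direction <- direction / nrm
  proj <- drop(coords %*% direction)
  if (stats::sd(proj) == 0 || stats::sd(signal) == 0)
    stop("undefined correlation: zero-variance projection or signal")
  list(r = stats::cor(proj, signal), projection = proj)
}
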