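# Shared numeric helpers.

# Pairwise squared Euclidean distances between rows of x (n x n).
pairwiseSqDist <- function(x) {
  d <- as.matrix(stats::dist(x))^2
  # dist() can leave tiny negative rounding on duplicates after squaring? no,
  # but be defensive against -0
  d[d < 0] <- 0
  d
}

# Squared distances between rows of a (n x p) and rows of b (m x p): n x m.
crossSqDist <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d[d < 0] <- 0
  d
}

# Fix eigenvector sign so the largest-magnitude entry is positive.
fixSigns <- function(v) {
  apply(v, 2, function(col) {
    i <- which.max(abs(col))
    if (col[i] < 0) -col else col
  })
}

# Population standard deviation (divide by n).
sdPop <- function(x) sqrt(mean((x - mean(x))^2))

# Z-score the rows (region time series) of a V x T matrix; errors on
# zero-variance rows, naming them.
zscoreRows <- function(x, what = "region") {
  m <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  if (any(s == 0)) {
    bad <- rownames(x)[s == 0]
    if (is.null(bad)) bad <- which(s == 0)
    stop("zero-variance ", what, "(s): ", paste(bad, collapse = ", "))
  }
  (x - m) / s
}

# Normalize rows to zero mean and unit Euclidean norm (hypersphere form used
# by the orthogonal synchronization); errors on constant rows.
normalizeRowsUnit <- function(x, what = "region") {
  m <- rowMeans(x)
  xc <- x - m
  nrm <- sqrt(rowSums(xc^2))
  if (any(nrm == 0)) {
    bad <- rownames(x)[nrm == 0]
    if (is.null(bad)) bad <- which(nrm == 0)
    stop("zero-variance ", what, "(s): ", paste(bad, collapse = ", "))
  }
  xc / nrm
}

# Random orthogonal matrix via QR of a Gaussian matrix, sign-corrected so the
# distribution is Haar.
randomOrthogonal <- function(n) {
  q <- qr(matrix(stats::rnorm(n * n), n, n))
  Q <- qr.Q(q)
  Q %*% diag(sign(diag(qr.R(q))), n)
}

#' Circular correlation of two angle vectors
#'
#' Fisher-Lee circular correlation coefficient; with `rank = TRUE` the angles
#' are first replaced by their uniform rank angles (2 * pi * rank / n), giving
#' a circular analogue of a rank correlation. Used to score how well an
#' embedding recovers the generating angle of points on a closed curve, where
#' the recovered angle is only defined up to rotation and reflection.
#'
#' @param a,b numeric vectors of angles (radians).
#' @param rank replace angles by rank angles first.
#' @return correlation in [-1, 1].
#' @export
circularCorrelation <- function(a, b, rank = TRUE) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (rank) {
    a <- 2 * pi * base::rank(a, ties.method = "average") / n
    b <- 2 * pi * base::rank(b, ties.method = "average") / n
  }
  da <- outer(a, a, "-")
  db <- outer(b, b, "-")
  num <- sum(sin(da) * sin(db))
  den <- sqrt(sum(sin(da)^2) * sum(sin(db)^2))
  if (den == 0) stop("degenerate angle vector")
  num / den
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical partitions, 0 is the expected value under independent
#' random labelings.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjustedRand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumij <- sum(comb2(tab))
  sumi <- sum(comb2(rowSums(tab)))
  sumj <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sumi * sumj / n2
  maxidx <- (sumi + sumj) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}
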