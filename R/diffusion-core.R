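#' Build a Gaussian-kernel affinity model and its random walk
#'
#' Constructs the pairwise similarity matrix S_ij = exp(-||x_i - x_j||^2 /
#' epsilon) over the rows of `x`, the row-stochastic random-walk operator
#' P = D^-1 S, and the walk's stationary distribution (degrees normalized to
#' sum one). This operator is the object every diffusion-map computation in
#' the package runs on.
#'
#' Three bandwidth strategies are available. `"median"` (the default) sets
#' epsilon to the median of all pairwise squared distances -- scale-free and
#' adequate for gently curved trajectories. `"knn"` sets epsilon to the median
#' squared distance to each point's `knn`-th nearest neighbour, a local scale
#' that is preferable when the manifold folds back on itself (e.g. a tightly
#' wrapped roll) and the global median would bridge separate sheets.
#' `"fixed"` uses the supplied `epsilon`.
#'
#' Duplicate points are allowed: a zero distance simply yields kernel value 1.
#'
#' @param x numeric matrix, one point per row (n >= 2, all finite).
#' @param kernelScale bandwidth strategy: "median", "knn" or "fixed".
#' @param epsilon bandwidth for `kernelScale = "fixed"` (> 0).
#' @param knn neighbour order for `kernelScale = "knn"`.
#' @return an [AffinityModel-class] object.
#' @examples
#' x <- matrix(c(0, 1), ncol = 1)
#' am <- buildAffinity(x, kernelScale = "fixed", epsilon = 1)
#' am@similarity[1, 2]  # exp(-1)
#' @export
buildAffinity <- function(x,
                          kernelScale = c("median", "knn", "fixed"),
                          epsilon = NULL,
                          knn = 15L) {
  kernelScale <- match.arg(kernelScale)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 points")
  if (!all(is.finite(x))) stop("invalid input: non-finite values in points")
  d2 <- pairwiseSqDist(x)
  eps <- switch(kernelScale,
    median = stats::median(d2[upper.tri(d2)]),
    knn = {
      k <- min(as.integer(knn), nrow(x) - 1L)
      stats::median(apply(d2, 1, function(r) sort(r)[k + 1L]))
    },
    fixed = {
      if (is.null(epsilon)) stop("epsilon must be given for fixed bandwidth")
      epsilon
    }
  )
  if (!is.finite(eps) || eps <= 0)
    stop("kernel bandwidth must be positive; got ", eps,
         " (degenerate point set?)")
  S <- exp(-d2 / eps)
  dimnames(S) <- NULL
  deg <- rowSums(S)
  P <- S / deg
  new("AffinityModel",
      points = x,
      similarity = S,
      kernelScale = eps,
      strategy = kernelScale,
      degrees = deg,
      randomWalk = P,
      stationary = deg / sum(deg))
}

#' Diffusion-map embedding of an affinity model
#'
#' Computes the top `nComponents` nontrivial right eigenpairs of the
#' random-walk operator P and the diffusion coordinates lambda_j^t * psi_j.
#' The computation runs on the symmetric conjugate D^-1/2 S D^-1/2 for
#' numerical stability and converts eigenvectors back to right eigenvectors of
#' P. Eigenvectors are scaled to unit stationary-weighted norm, under which
#' Euclidean distance in the full (n-1)-dimensional embedding reproduces the
#' diffusion distance exactly, and signs are fixed so each eigenvector's
#' largest-magnitude entry is positive.
#'
#' The trivial eigenpair -- eigenvalue closest to 1 with a constant
#' eigenvector (coefficient of variation < 1e-6) -- is dropped; if no
#' eigenpair qualifies an error is raised.
#'
#' @param model an [AffinityModel-class].
#' @param nComponents number of embedding dimensions k, 1 <= k <= n - 1.
#' @param diffusionTime diffusion time t >= 1.
#' @return a [DiffusionEmbedding-class].
#' @export
diffusionEmbed <- function(model, nComponents, diffusionTime = 1L) {
  stopifnot(is(model, "AffinityModel"))
  n <- nrow(model@similarity)
  k <- as.integer(nComponents)
  t <- as.integer(diffusionTime)
  if (k < 1L || k > n - 1L) stop("nComponents must be in [1, n - 1]")
  if (t < 1L) stop("diffusionTime must be >= 1")

  dhalf <- sqrt(model@degrees)
  A <- model@similarity / outer(dhalf, dhalf)
  es <- tryCatch(eigen(A, symmetric = TRUE),
                 error = function(e) stop("eigensolver failure: ",
                                          conditionMessage(e)))
  lam <- es$values
  # clamp tiny numerical excursions outside the spectral bound
  lam[lam > 1 & lam < 1 + 1e-10] <- 1
  lam[lam < -1 & lam > -1 - 1e-10] <- -1
  U <- es$vectors

  # The trivial eigenvector of A is known in closed form: D^(1/2) 1. When the
  # top eigenvalue is numerically degenerate (near-disconnected graphs) the
  # eigensolver returns an arbitrary rotation of that eigenspace, so the
  # constant vector lives in its span without being any single returned
  # column. Rotate the near-top group so its first basis vector is exactly
  # the known trivial one, then drop it.
  uc <- dhalf / sqrt(sum(dhalf^2))
  ord <- order(lam, decreasing = TRUE)
  grp <- ord[abs(lam[ord] - lam[ord[1]]) < 1e-8]
  pr <- drop(crossprod(U[, grp, drop = FALSE], uc))
  if (sum(pr^2) < 1 - 1e-6)
    stop("no trivial eigenpair found: leading eigenvector is not constant")
  if (length(grp) > 1L) {
    rot <- qr.Q(qr(cbind(pr, diag(length(grp)))))[, seq_along(grp)]
    if (sum(rot[, 1] * pr) < 0) rot[, 1] <- -rot[, 1]
    U[, grp] <- U[, grp, drop = FALSE] %*% rot
  }
  trivial <- grp[1]

  psi <- U / dhalf
  # unit stationary-weighted norm: sum(phi0 * psi_j^2) = 1
  pi0 <- model@stationary
  scl <- sqrt(colSums(pi0 * psi^2))
  psi <- sweep(psi, 2, scl, "/")
  cv <- stats::sd(psi[, trivial]) / abs(mean(psi[, trivial]))
  if (!is.finite(cv) || cv > 1e-6)
    stop("no trivial eigenpair found: leading eigenvector is not constant")
  keep <- setdiff(ord, trivial)[seq_len(k)]
  lam_k <- lam[keep]
  psi_k <- fixSigns(psi[, keep, drop = FALSE])
  new("DiffusionEmbedding",
      eigenvalues = lam_k,
      eigenvectors = psi_k,
      diffusionTime = t,
      coordinates = sweep(psi_k, 2, lam_k^t, "*"))
}

#' Brute-force diffusion distance between two points
#'
#' Evaluates the diffusion distance directly from its definition: P is powered
#' to t explicitly and D_t^2(x_i, x_j) = sum_z (p_t(x_i, z) - p_t(x_j, z))^2 /
#' phi0(z) is summed term by term, phi0 being the stationary distribution.
#' This is the independent oracle against which the spectral embedding
#' distances are checked; it is exact but O(n^3 t).
#'
#' @param model an [AffinityModel-class].
#' @param t diffusion time (>= 1).
#' @param i,j point indices.
#' @return the (nonnegative) diffusion distance D_t(x_i, x_j).
#' @export
diffusionDistance <- function(model, t, i, j) {
  stopifnot(is(model, "AffinityModel"))
  n <- nrow(model@randomWalk)
  t <- as.integer(t)
  if (t < 1L) stop("t must be >= 1")
  if (i < 1L || i > n || j < 1L || j > n) stop("index out of range")
  pi0 <- model@stationary
  if (any(pi0 <= 0)) stop("degenerate model: zero stationary entry")
  Pt <- model@randomWalk
  if (t > 1L) for (s in seq_len(t - 1L)) Pt <- Pt %*% model@randomWalk
  sqrt(sum((Pt[i, ] - Pt[j, ])^2 / pi0))
}
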