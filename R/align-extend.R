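#' Orthogonal temporal synchronization of one scan to a reference
#'
#' Aligns a moving scan Y to a reference scan X (both V x T, same regions and
#' frame count) by the orthogonal Procrustes rotation in time: each region's
#' series is normalized to zero mean and unit norm (so frames lie on a
#' hypersphere), the temporal cross-correlation X^t Y is formed, and its SVD
#' U Sigma V^t gives the Kabsch solution O_s = U V^t. The synchronized scan is
#' Y O_s^t; the residual ||X - Y O_s^t||_F never exceeds the pre-rotation
#' residual.
#'
#' @param moving V x T matrix to be rotated.
#' @param reference V x T reference matrix.
#' @param referenceSubject optional label stored in the result.
#' @return a [SyncTransform-class]; the synchronized scan is in
#'   `synchronizedSeries(result)` (rows zero-mean, unit-norm).
#' @export
brainSync <- function(moving, reference, referenceSubject = "reference") {
  moving <- as.matrix(moving); reference <- as.matrix(reference)
  if (!identical(dim(moving), dim(reference)))
    stop("invalid input: moving and reference must share dimensions")
  X <- normalizeRowsUnit(reference)
  Y <- normalizeRowsUnit(moving)
  C <- crossprod(X, Y)  # T x T temporal cross-correlation
  # Row centering puts both scans orthogonal to the constant vector, so C is
  # always singular along it and U V^t would pick an arbitrary action there.
  # Solve the Procrustes problem on the complement and act as the identity on
  # the constant direction: canonical, and Y = X then recovers the identity.
  Tn <- ncol(C)
  ones <- rep(1 / sqrt(Tn), Tn)
  B <- qr.Q(qr(cbind(ones, diag(Tn))))[, 2:Tn, drop = FALSE]
  sv <- svd(crossprod(B, C %*% B))
  Os <- B %*% tcrossprod(sv$u %*% t(sv$v), B) + tcrossprod(ones)
  sync <- Y %*% t(Os)
  new("SyncTransform",
      rotation = Os,
      referenceSubject = as.character(referenceSubject),
      residual = sqrt(sum((X - sync)^2)),
      synchronized = sync)
}

#' Nystrom out-of-sample extension of a diffusion embedding
#'
#' Assigns embedding coordinates to points not in the training set by kernel
#' interpolation: for each new point y the kernel row w(y, x_i) is evaluated
#' with the training bandwidth, row-normalized to transition probabilities
#' p(y, .), and each eigenvector is extended as psi_hat_j(y) = (1 / lambda_j)
#' * sum_i p(y, x_i) psi_j(x_i); coordinates carry the lambda_j^t weights of
#' the training embedding. Extending a training point reproduces its training
#' coordinates exactly.
#'
#' New points far from every training point (total kernel mass < 1e-6) are
#' flagged with a warning: their normalized kernel row is numerically
#' meaningless and the extension unreliable.
#'
#' @param affinity the training [AffinityModel-class].
#' @param embedding the training [DiffusionEmbedding-class].
#' @param newPoints n' x p matrix, same feature dimension as training points.
#' @return n' x k matrix of extended coordinates.
#' @export
nystromExtend <- function(affinity, embedding, newPoints) {
  stopifnot(is(affinity, "AffinityModel"), is(embedding, "DiffusionEmbedding"))
  newPoints <- as.matrix(newPoints)
  if (ncol(newPoints) != ncol(affinity@points))
    stop("invalid input: new points must share the training feature dimension")
  lam <- embedding@eigenvalues
  if (any(abs(lam) < 1e-12))
    stop("extension unstable: near-zero eigenvalue(s) at component(s) ",
         paste(which(abs(lam) < 1e-12), collapse = ", "))
  W <- exp(-crossSqDist(newPoints, affinity@points) / affinity@kernelScale)
  mass <- rowSums(W)
  if (any(mass < 1e-6))
    warning("low kernel mass for new point(s) ",
            paste(which(mass < 1e-6), collapse = ", "),
            "; extension may be unreliable")
  Prow <- W / mass
  # psi_hat * lambda^t = P psi lambda^(t-1)
  Prow %*% embedding@eigenvectors %*%
    diag(lam^(embedding@diffusionTime - 1L), length(lam))
}

#' Two-step out-of-sample extension onto a trained group manifold
#'
#' Extends new frames from the same subjects onto an existing
#' [TwoStepEmbedding-class]: stage-1 Nystrom extension per subject, feature
#' concatenation in training subject order, then stage-2 Nystrom extension
#' onto the group embedding. If the new data are not task-synchronized (e.g.
#' resting scans), give `syncReference`: every other subject's new scan is
#' first rotated to that subject's scan with [brainSync()].
#'
#' New scans are normalized exactly as the training scans were (per-region
#' z-score within scan) before the stage-1 kernel rows are evaluated.
#'
#' @param training a [TwoStepEmbedding-class] fitted by [twoStepDM()].
#' @param newTensor a [GroupTensor-class] (or M x V x T' array) with the same
#'   subjects in the same order.
#' @param syncReference optional subject id (or index) used as the BrainSync
#'   reference; NULL means the new data are already synchronized.
#' @param zscore z-score regions within each new scan (must match training).
#' @return an [ExtendedCoordinates-class].
#' @export
twoStepOOSE <- function(training, newTensor, syncReference = NULL,
                        zscore = TRUE) {
  stopifnot(is(training, "TwoStepEmbedding"))
  if (is(newTensor, "GroupTensor")) {
    arr <- newTensor@data
    ids <- newTensor@subjectIds
  } else {
    arr <- newTensor
    ids <- training@subjectIds
  }
  M <- length(training@stage1)
  if (dim(arr)[1] != M || !identical(ids, training@subjectIds))
    stop("invalid input: subjects must match the training embedding")

  scans <- lapply(seq_len(M), function(m) arr[m, , ])
  if (!is.null(syncReference)) {
    ref <- if (is.character(syncReference))
      match(syncReference, training@subjectIds) else as.integer(syncReference)
    if (is.na(ref) || ref < 1L || ref > M)
      stop("invalid input: unknown sync reference subject")
    for (m in seq_len(M)) {
      if (m == ref) next
      scans[[m]] <- synchronizedSeries(
        brainSync(scans[[m]], scans[[ref]],
                  referenceSubject = training@subjectIds[ref]))
    }
  }

  stage1Ext <- vector("list", M)
  for (m in seq_len(M)) {
    x <- scans[[m]]
    if (zscore) x <- zscoreRows(x)
    stage1Ext[[m]] <- nystromExtend(training@stage1Affinity[[m]],
                                    training@stage1[[m]], t(x))
  }
  concatExt <- do.call(cbind, stage1Ext)
  stage2Ext <- nystromExtend(training@stage2Affinity, training@stage2,
                             concatExt)
  new("ExtendedCoordinates",
      stage1Ext = stage1Ext,
      stage2Ext = stage2Ext,
      subjectIds = training@subjectIds)
}
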