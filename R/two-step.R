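#' Construct a GroupTensor
#'
#' Assembles an M x V x T array of per-subject region time series into the
#' container the two-step embedding consumes.
#'
#' @param data numeric M x V x T array (subjects x regions x time).
#' @param subjectIds,regionIds,frameIndex optional labels; defaults generated.
#' @param synchronized are frames task-synchronized across subjects?
#' @return a [GroupTensor-class].
#' @export
GroupTensor <- function(data, subjectIds = NULL, regionIds = NULL,
                        frameIndex = NULL, synchronized = TRUE) {
  d <- dim(data)
  if (is.null(subjectIds)) subjectIds <- sprintf("sub%02d", seq_len(d[1]))
  if (is.null(regionIds)) regionIds <- sprintf("r%03d", seq_len(d[2]))
  if (is.null(frameIndex)) frameIndex <- seq_len(d[3])
  new("GroupTensor", data = data,
      subjectIds = as.character(subjectIds),
      regionIds = as.character(regionIds),
      frameIndex = as.integer(frameIndex),
      synchronized = isTRUE(synchronized))
}

# Internal: stage-1 embedding of one subject's V x T series; returns both the
# affinity model (needed later for out-of-sample extension) and the embedding.
.embedFrames <- function(series, d1, kernelScale, epsilon, knn,
                         diffusionTime, zscore) {
  if (zscore) series <- zscoreRows(series)
  frames <- t(series)  # T frames as points in R^V
  if (nrow(unique(frames)) == 1L)
    stop("degenerate input: all time frames identical")
  am <- buildAffinity(frames, kernelScale = kernelScale, epsilon = epsilon,
                      knn = knn)
  list(affinity = am,
       embedding = diffusionEmbed(am, nComponents = d1,
                                  diffusionTime = diffusionTime))
}

#' Temporal diffusion embedding of a single subject's frames
#'
#' Treats the T time frames (columns of a V x T region-by-time matrix) as
#' points in R^V and embeds them with diffusion maps into d1 dimensions --
#' the first stage of the two-step framework. Each region's time series is
#' z-scored first by default, so no single high-amplitude region dominates
#' the frame geometry.
#'
#' @param series V x T numeric matrix (regions x time).
#' @param d1 embedding dimensionality, at most T - 1.
#' @param kernelScale,epsilon,knn bandwidth choice, see [buildAffinity()].
#' @param diffusionTime diffusion time t.
#' @param zscore z-score each region's series before the kernel.
#' @return a [DiffusionEmbedding-class] with T rows and d1 columns.
#' @export
embedSubjectFrames <- function(series, d1,
                               kernelScale = c("median", "knn", "fixed"),
                               epsilon = NULL, knn = 15L,
                               diffusionTime = 1L, zscore = TRUE) {
  kernelScale <- match.arg(kernelScale)
  series <- as.matrix(series)
  if (d1 > ncol(series) - 1L) stop("d1 must be at most T - 1")
  .embedFrames(series, d1, kernelScale, epsilon, knn, diffusionTime,
               zscore)$embedding
}

#' Two-step diffusion-map embedding of a group tensor
#'
#' The hierarchical group embedding: each subject's time frames are embedded
#' independently into d1 dimensions (stage 1), the per-subject coordinates are
#' concatenated along the feature axis so each frame is represented by all
#' subjects' embeddings, and a second diffusion map reduces the concatenated
#' frames to d2 dimensions (stage 2). Distances in the stage-2 embedding
#' approximate the average diffusion distance between time frames across
#' subjects. Defaults d1 = 7 and d2 = 3.
#'
#' The bandwidth is chosen independently at each stage and for each subject,
#' since the two stages operate at different scales. Stage-1 coordinates are
#' concatenated with their lambda^t weights as-is, preserving each subject's
#' spectral-gap information.
#'
#' @param tensor a synchronized [GroupTensor-class].
#' @param d1,d2 stage dimensionalities (each at most T - 1).
#' @param kernelScale,knn bandwidth strategy applied at both stages.
#' @param diffusionTime diffusion time t for both stages.
#' @param zscore z-score regions within subject before stage 1.
#' @return a [TwoStepEmbedding-class].
#' @export
twoStepDM <- function(tensor, d1 = 7L, d2 = 3L,
                      kernelScale = c("median", "knn", "fixed"),
                      epsilon = NULL, knn = 15L,
                      diffusionTime = 1L, zscore = TRUE) {
  stopifnot(is(tensor, "GroupTensor"))
  kernelScale <- match.arg(kernelScale)
  if (!tensor@synchronized)
    stop("tensor is not synchronized across subjects; apply brainSync() ",
         "to a common reference first")
  d <- dim(tensor@data)
  M <- d[1]; Tn <- d[3]
  d1 <- as.integer(d1); d2 <- as.integer(d2)
  if (d1 > Tn - 1L || d2 > Tn - 1L) stop("d1 and d2 must be at most T - 1")
  if (d1 * M < d2) stop("d1 * M must be at least d2")

  stage1 <- vector("list", M)
  stage1Aff <- vector("list", M)
  for (m in seq_len(M)) {
    fit <- .embedFrames(tensor@data[m, , ], d1, kernelScale, epsilon, knn,
                        diffusionTime, zscore)
    stage1[[m]] <- fit$embedding
    stage1Aff[[m]] <- fit$affinity
  }
  concat <- do.call(cbind, lapply(stage1, embCoordinates))  # T x (M*d1)
  am2 <- buildAffinity(concat, kernelScale = kernelScale, epsilon = epsilon,
                       knn = knn)
  emb2 <- diffusionEmbed(am2, nComponents = d2, diffusionTime = diffusionTime)
  new("TwoStepEmbedding",
      stage1 = stage1, stage1Affinity = stage1Aff,
      concatenated = concat,
      stage2Affinity = am2, stage2 = emb2,
      d1 = d1, d2 = d2,
      subjectIds = tensor@subjectIds,
      frameIndex = tensor@frameIndex)
}

#' Two-step PCA baseline embedding
#'
#' Linear counterpart of [twoStepDM()] used as the comparison baseline:
#' per-subject PCA of the time frames (frames centered across time, top d1
#' component scores kept), concatenation across subjects, and a second PCA to
#' d2 dimensions. Rank-deficient subjects are zero-padded to d1 components
#' with a warning rather than aborting.
#'
#' @param tensor a synchronized [GroupTensor-class].
#' @param d1,d2 stage dimensionalities.
#' @param zscore z-score regions within subject first (matching the
#'   pre-processing used for the diffusion variant).
#' @return a [LinearTwoStepEmbedding-class].
#' @export
twoStepPCA <- function(tensor, d1 = 7L, d2 = 3L, zscore = TRUE) {
  stopifnot(is(tensor, "GroupTensor"))
  if (!tensor@synchronized)
    stop("tensor is not synchronized across subjects; apply brainSync() ",
         "to a common reference first")
  d <- dim(tensor@data)
  M <- d[1]; Tn <- d[3]
  d1 <- as.integer(d1); d2 <- as.integer(d2)
  if (d1 > Tn - 1L || d2 > Tn - 1L) stop("d1 and d2 must be at most T - 1")

  scores <- vector("list", M)
  for (m in seq_len(M)) {
    x <- tensor@data[m, , ]
    if (zscore) x <- zscoreRows(x)
    frames <- t(x)
    pc <- stats::prcomp(frames, center = TRUE, scale. = FALSE)
    avail <- sum(pc$sdev > max(pc$sdev) * 1e-8)  # numerical rank
    if (avail < d1) {
      warning(sprintf("subject %s has rank %d < d1 = %d; zero-padding",
                      tensor@subjectIds[m], avail, d1))
      sc <- cbind(pc$x[, seq_len(avail), drop = FALSE],
                  matrix(0, Tn, d1 - avail))
    } else {
      sc <- pc$x[, seq_len(d1), drop = FALSE]
    }
    scores[[m]] <- sc
  }
  concat <- do.call(cbind, scores)
  pc2 <- stats::prcomp(concat, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(d2, ncol(pc2$x)))
  new("LinearTwoStepEmbedding",
      stage1Scores = scores,
      concatenated = concat,
      stage2Scores = pc2$x[, keep, drop = FALSE],
      stage2Loadings = pc2$rotation[, keep, drop = FALSE],
      center = pc2$center,
      explainedVariance = pc2$sdev[keep]^2)
}
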