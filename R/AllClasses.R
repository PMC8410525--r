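#' @import methods
NULL

#' AffinityModel: Gaussian-kernel random walk over a point set
#'
#' Holds the symmetric Gaussian-kernel similarity matrix over a set of points,
#' its row-normalized random-walk operator, the degrees and the stationary
#' distribution of the walk. Produced by [buildAffinity()] and consumed by
#' [diffusionEmbed()], [diffusionDistance()] and [nystromExtend()].
#'
#' @slot points numeric matrix, n points in rows.
#' @slot similarity n x n symmetric kernel matrix S with unit diagonal.
#' @slot kernelScale the Gaussian bandwidth epsilon actually used.
#' @slot strategy how the bandwidth was chosen ("median", "knn" or "fixed").
#' @slot degrees row sums of S (all positive).
#' @slot randomWalk the row-stochastic operator P = D^-1 S.
#' @slot stationary degrees normalized to sum one; the left fixed point of P.
#'
#' @export
setClass("AffinityModel",
  representation(
    points = "matrix",
    similarity = "matrix",
    kernelScale = "numeric",
    strategy = "character",
    degrees = "numeric",
    randomWalk = "matrix",
    stationary = "numeric"
  )
)

setValidity("AffinityModel", function(object) {
  S <- object@similarity
  n <- nrow(S)
  msg <- character()
  if (n < 2L) msg <- c(msg, "at least 2 points required")
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-10)))
    msg <- c(msg, "similarity matrix must be symmetric")
  if (any(S <= 0) || any(S > 1 + 1e-12))
    msg <- c(msg, "similarity entries must lie in (0, 1]")
  if (max(abs(diag(S) - 1)) > 1e-12)
    msg <- c(msg, "similarity diagonal must be 1")
  if (any(object@degrees <= 0)) msg <- c(msg, "all degrees must be positive")
  if (max(abs(rowSums(object@randomWalk) - 1)) > 1e-10)
    msg <- c(msg, "random-walk rows must sum to 1")
  pi0 <- object@stationary
  if (abs(sum(pi0) - 1) > 1e-10 || any(pi0 < 0))
    msg <- c(msg, "stationary must be a probability vector")
  if (max(abs(drop(pi0 %*% object@randomWalk) - pi0)) > 1e-8)
    msg <- c(msg, "stationary must be a left fixed point of the random walk")
  if (length(msg)) msg else TRUE
})

#' DiffusionEmbedding: spectral coordinates of a random walk
#'
#' Top nontrivial right eigenpairs of a random-walk operator together with the
#' diffusion-time-weighted coordinates lambda_j^t * psi_j. The trivial pair
#' (lambda = 1, constant eigenvector) is excluded. Eigenvectors are normalized
#' so that the stationary-weighted norm is one, which makes Euclidean distance
#' in the full embedding equal the diffusion distance.
#'
#' @slot eigenvalues nontrivial eigenvalues, sorted descending, all in [-1, 1].
#' @slot eigenvectors n x k matrix of right eigenvectors psi_1..psi_k.
#' @slot diffusionTime positive integer diffusion time t.
#' @slot coordinates n x k matrix; column j is eigenvalues[j]^t * psi_j.
#'
#' @export
setClass("DiffusionEmbedding",
  representation(
    eigenvalues = "numeric",
    eigenvectors = "matrix",
    diffusionTime = "integer",
    coordinates = "matrix"
  )
)

setValidity("DiffusionEmbedding", function(object) {
  msg <- character()
  k <- length(object@eigenvalues)
  if (ncol(object@eigenvectors) != k || ncol(object@coordinates) != k)
    msg <- c(msg, "eigenvector/coordinate columns must match eigenvalue count")
  if (k >= nrow(object@eigenvectors))
    msg <- c(msg, "k must be smaller than the number of points")
  if (any(abs(object@eigenvalues) > 1 + 1e-10))
    msg <- c(msg, "eigenvalues must lie in [-1, 1]")
  if (length(object@eigenvalues) > 1 && any(diff(object@eigenvalues) > 1e-12))
    msg <- c(msg, "eigenvalues must be sorted descending")
  if (object@diffusionTime < 1L) msg <- c(msg, "diffusion time must be >= 1")
  expected <- sweep(object@eigenvectors, 2,
                    object@eigenvalues^object@diffusionTime, "*")
  if (max(abs(expected - object@coordinates)) > 1e-8)
    msg <- c(msg, "coordinates must equal lambda^t-weighted eigenvectors")
  if (length(msg)) msg else TRUE
})

#' GroupTensor: subjects x regions x time functional data
#'
#' The three-dimensional array of parcellated time series that the two-step
#' embedding consumes: M subjects, V regions, T time frames, all subjects
#' sharing the same frame grid. The `synchronized` flag records whether the
#' frames are task-synchronized across subjects (required for [twoStepDM()];
#' use [brainSync()] first otherwise).
#'
#' @slot data numeric M x V x T array.
#' @slot subjectIds character, length M.
#' @slot regionIds character, length V.
#' @slot frameIndex integer, length T.
#' @slot synchronized logical flag.
#'
#' @export
setClass("GroupTensor",
  representation(
    data = "array",
    subjectIds = "character",
    regionIds = "character",
    frameIndex = "integer",
    synchronized = "logical"
  )
)

setValidity("GroupTensor", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L) return("data must be a 3-d array (subjects x regions x time)")
  if (d[1] < 1L || d[2] < 2L || d[3] < 3L)
    msg <- c(msg, "need M >= 1, V >= 2, T >= 3")
  if (!all(is.finite(object@data))) msg <- c(msg, "all values must be finite")
  if (length(object@subjectIds) != d[1]) msg <- c(msg, "subjectIds length != M")
  if (length(object@regionIds) != d[2]) msg <- c(msg, "regionIds length != V")
  if (length(object@frameIndex) != d[3]) msg <- c(msg, "frameIndex length != T")
  if (length(msg)) msg else TRUE
})

#' TwoStepEmbedding: hierarchical group embedding of time frames
#'
#' Result of [twoStepDM()]: per-subject stage-1 diffusion embeddings of the T
#' time frames (d1 coordinates each), their feature-wise concatenation, and the
#' stage-2 diffusion embedding of the concatenated frames (d2 coordinates).
#' The stage-1 and stage-2 affinity models are retained so new frames can be
#' extended onto the manifold with [twoStepOOSE()].
#'
#' @slot stage1 list of M `DiffusionEmbedding` objects (T x d1 coordinates).
#' @slot stage1Affinity list of M `AffinityModel` objects.
#' @slot concatenated T x (M*d1) matrix of stacked stage-1 coordinates.
#' @slot stage2Affinity `AffinityModel` over the concatenated frames.
#' @slot stage2 `DiffusionEmbedding` with the final T x d2 coordinates.
#' @slot d1,d2 stage dimensionalities.
#' @slot subjectIds character, length M.
#' @slot frameIndex integer, length T.
#'
#' @export
setClass("TwoStepEmbedding",
  representation(
    stage1 = "list",
    stage1Affinity = "list",
    concatenated = "matrix",
    stage2Affinity = "AffinityModel",
    stage2 = "DiffusionEmbedding",
    d1 = "integer",
    d2 = "integer",
    subjectIds = "character",
    frameIndex = "integer"
  )
)

setValidity("TwoStepEmbedding", function(object) {
  msg <- character()
  M <- length(object@stage1)
  if (ncol(object@concatenated) != M * object@d1)
    msg <- c(msg, "concatenated must have M*d1 columns")
  co <- object@stage2@coordinates
  if (nrow(co) != nrow(object@concatenated) || ncol(co) != object@d2)
    msg <- c(msg, "stage-2 coordinates must be T x d2")
  if (length(msg)) msg else TRUE
})

#' LinearTwoStepEmbedding: matched two-step PCA baseline
#'
#' Linear analogue of [TwoStepEmbedding-class] produced by [twoStepPCA()]:
#' per-subject PCA scores of the time frames, concatenated and reduced again
#' by a second PCA. Stage-2 loadings and center are retained so frames can be
#' reconstructed from their stage-2 scores.
#'
#' @slot stage1Scores list of M T x d1 score matrices.
#' @slot concatenated T x (M*d1) matrix.
#' @slot stage2Scores T x d2 matrix.
#' @slot stage2Loadings (M*d1) x d2 orthonormal loadings.
#' @slot center length M*d1 column means removed before the second PCA.
#' @slot explainedVariance stage-2 component variances, sorted descending.
#'
#' @export
setClass("LinearTwoStepEmbedding",
  representation(
    stage1Scores = "list",
    concatenated = "matrix",
    stage2Scores = "matrix",
    stage2Loadings = "matrix",
    center = "numeric",
    explainedVariance = "numeric"
  )
)

setValidity("LinearTwoStepEmbedding", function(object) {
  msg <- character()
  ev <- object@explainedVariance
  if (any(ev < 0))
    msg <- c(msg, "explainedVariance must be nonnegative")
  if (length(ev) > 1 && any(diff(ev) > 1e-10))
    msg <- c(msg, "explainedVariance must be sorted descending")
  G <- crossprod(object@stage2Loadings)
  if (max(abs(G - diag(ncol(G)))) > 1e-8)
    msg <- c(msg, "stage-2 loadings must be orthonormal")
  if (length(msg)) msg else TRUE
})

#' SyncTransform: orthogonal temporal alignment of one scan to a reference
#'
#' The T x T orthogonal rotation found by [brainSync()] (Kabsch solution of the
#' orthogonal Procrustes problem on row-normalized region time series), the
#' synchronized scan, and the Frobenius residual after alignment.
#'
#' @slot rotation T x T orthogonal matrix O_s.
#' @slot referenceSubject label of the reference scan.
#' @slot residual Frobenius norm of (reference - synchronized).
#' @slot synchronized the moving scan after rotation, V x T.
#'
#' @export
setClass("SyncTransform",
  representation(
    rotation = "matrix",
    referenceSubject = "character",
    residual = "numeric",
    synchronized = "matrix"
  )
)

setValidity("SyncTransform", function(object) {
  O <- object@rotation
  msg <- character()
  if (max(abs(crossprod(O) - diag(ncol(O)))) > 1e-8)
    msg <- c(msg, "rotation must be orthogonal")
  if (object@residual < 0) msg <- c(msg, "residual must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' ExtendedCoordinates: out-of-sample frames on a trained manifold
#'
#' Nystrom-extended coordinates for T' new frames produced by [twoStepOOSE()]:
#' per-subject stage-1 extensions and the final stage-2 extension.
#'
#' @slot stage1Ext list of M T' x d1 matrices.
#' @slot stage2Ext T' x d2 matrix.
#' @slot subjectIds character, length M.
#'
#' @export
setClass("ExtendedCoordinates",
  representation(
    stage1Ext = "list",
    stage2Ext = "matrix",
    subjectIds = "character"
  )
)

#' DynamicConnectivity: windowed MTD edge weights
#'
#' Sliding-window dynamic connectivity from the multiplication of temporal
#' derivatives: a V x V x Tw array of symmetric edge-weight slices, the window
#' length, and the map from connectivity frames back to original time frames.
#'
#' @slot weights V x V x Tw numeric array; each slice symmetric.
#' @slot windowLength window length w.
#' @slot frameMap integer; original (1-based) frame index at which each
#'   window's first temporal derivative is taken.
#' @slot regionIds character, length V.
#'
#' @export
setClass("DynamicConnectivity",
  representation(
    weights = "array",
    windowLength = "integer",
    frameMap = "integer",
    regionIds = "character"
  )
)

setValidity("DynamicConnectivity", function(object) {
  d <- dim(object@weights)
  msg <- character()
  if (length(d) != 3L || d[1] != d[2])
    return("weights must be a V x V x Tw array")
  if (length(object@frameMap) != d[3])
    msg <- c(msg, "frameMap length must equal the number of windows")
  if (length(msg)) msg else TRUE
})

#' CommunityPartition: time-resolved module assignments
#'
#' Louvain community labels per node per connectivity frame.
#'
#' @slot labels V x Tw integer matrix of module ids.
#' @slot nModules integer, modules per frame.
#' @slot seed RNG seed used.
#' @slot resolution Louvain resolution parameter.
#'
#' @export
setClass("CommunityPartition",
  representation(
    labels = "matrix",
    nModules = "integer",
    seed = "integer",
    resolution = "numeric"
  )
)

setValidity("CommunityPartition", function(object) {
  if (any(object@nModules < 1L)) "every frame needs at least one module" else TRUE
})

#' ParticipationSeries: node and whole-brain participation coefficients
#'
#' Per-node participation coefficients B_i over connectivity frames and their
#' across-node mean B_T (whole-brain integration index).
#'
#' @slot nodePC V x Tw matrix, values in [0, 1].
#' @slot globalPC length-Tw mean over nodes.
#' @slot frameMap integer frame map inherited from the connectivity object.
#'
#' @export
setClass("ParticipationSeries",
  representation(
    nodePC = "matrix",
    globalPC = "numeric",
    frameMap = "integer"
  )
)

setValidity("ParticipationSeries", function(object) {
  msg <- character()
  if (any(object@nodePC < -1e-12) || any(object@nodePC > 1 + 1e-12))
    msg <- c(msg, "participation coefficients must lie in [0, 1]")
  if (max(abs(colMeans(object@nodePC) - object@globalPC)) > 1e-10)
    msg <- c(msg, "globalPC must be the mean of nodePC over nodes")
  if (length(msg)) msg else TRUE
})

#' StateModel: discrete brain states from k-means on embedding coordinates
#'
#' Frame-to-state labels, centroids and Calinski-Harabasz scores from seeded
#' k-means on embedding coordinates. Retains the coordinates so out-of-sample
#' frames can inherit states from their nearest reference frame.
#'
#' @slot k number of states.
#' @slot labels integer state per frame, in 1..k.
#' @slot centroids k x d matrix of state means.
#' @slot chScores named numeric, Calinski-Harabasz score per evaluated k.
#' @slot seed RNG seed used.
#' @slot coords the T x d coordinates that were clustered.
#'
#' @export
setClass("StateModel",
  representation(
    k = "integer",
    labels = "integer",
    centroids = "matrix",
    chScores = "numeric",
    seed = "integer",
    coords = "matrix"
  )
)

setValidity("StateModel", function(object) {
  msg <- character()
  if (any(object@labels < 1L) || any(object@labels > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  for (s in seq_len(object@k)) {
    idx <- object@labels == s
    if (any(idx)) {
      m <- colMeans(object@coords[idx, , drop = FALSE])
      if (max(abs(m - object@centroids[s, ])) > 1e-8)
        msg <- c(msg, sprintf("centroid %d is not the mean of its frames", s))
    }
  }
  if (length(msg)) msg else TRUE
})

#' TransitionModel: Markov structure of state sequences
#'
#' Row-stochastic transition matrix estimated from temporally adjacent state
#' labels, its stationary distribution (dwell-time distribution), per-state
#' outgoing-transition entropy (nats) and per-state frame counts.
#'
#' @slot transition k x k row-stochastic matrix.
#' @slot stationary length-k probability vector, left fixed point.
#' @slot entropy length-k nonnegative, bounded by log k.
#' @slot dwellCounts integer frames per state.
#' @slot unreliableStates integer ids of states with few outgoing transitions.
#'
#' @export
setClass("TransitionModel",
  representation(
    transition = "matrix",
    stationary = "numeric",
    entropy = "numeric",
    dwellCounts = "integer",
    unreliableStates = "integer"
  )
)

setValidity("TransitionModel", function(object) {
  P <- object@transition
  msg <- character()
  rs <- rowSums(P)
  ok <- rs > 0  # flagged absorbing-free rows may be all zero
  if (any(abs(rs[ok] - 1) > 1e-10))
    msg <- c(msg, "transition rows must sum to 1")
  k <- nrow(P)
  if (any(object@entropy < -1e-12) || any(object@entropy > log(k) + 1e-8))
    msg <- c(msg, "entropy must lie in [0, log k]")
  if (length(msg)) msg else TRUE
})
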