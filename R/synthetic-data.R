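#' Simulate a multi-subject tensor with known latent structure
#'
#' Generates M time-synchronized subjects whose region x time matrices share a
#' low-dimensional latent trajectory: subject i's signal is mixing_i %*%
#' t(latent) plus Gaussian noise scaled so that each region's signal-to-noise
#' ratio (signal SD / noise SD) equals `snr`. Everything is reproducible from
#' `seed`.
#'
#' Latent kinds:
#' \describe{
#'   \item{arc}{half-circle trajectory (cos, sin of theta in [0, pi]),
#'     uniformly spaced; truth parameter is theta.}
#'   \item{circle}{full circle, T equally spaced angles; truth is the angle.}
#'   \item{swiss_roll}{(u cos u, h, u sin u) with u sorted-uniform on
#'     [1.5 pi, 3.5 pi] and height h uniform on [0, 6]; truth is the
#'     unrolled arclength parameter u.}
#'   \item{markov_states}{a k-state chain drawn from `transitionTruth`
#'     (default: 0.8 self-transition, remainder uniform); the latent is the
#'     state's Gaussian mean (means drawn with SD 4 in `latentDim`
#'     dimensions, within-state jitter SD 0.5); truth includes the labels.}
#' }
#'
#' @param M,V,T subjects, regions, frames.
#' @param latentKind one of "arc", "circle", "swiss_roll", "markov_states".
#' @param latentDim latent dimensionality for "markov_states" (others fix
#'   their own).
#' @param nStates,transitionTruth chain order and row-stochastic truth matrix
#'   for "markov_states".
#' @param mixing "orthogonal" (orthonormal columns via QR) or "gaussian".
#' @param snr per-region signal-SD / noise-SD ratio (> 0; Inf = noiseless).
#' @param arCoef optional AR(1) coefficient for temporally correlated noise.
#' @param blockDesign optional data.frame with columns `block`, `length`,
#'   `repetitions`; blocks are laid out cyclically and must fill T exactly.
#' @param seed RNG seed.
#' @return list with `tensor` (a [GroupTensor-class]) and `truth` (list with
#'   `latent`, `param`, `stateLabels`, `mixing`, `design`).
#' @export
simulateGroupTensor <- function(M = 8L, V = 60L, T = 300L,
                                latentKind = c("arc", "circle", "swiss_roll",
                                               "markov_states"),
                                latentDim = 3L, nStates = 4L,
                                transitionTruth = NULL,
                                mixing = c("orthogonal", "gaussian"),
                                snr = 5, arCoef = 0,
                                blockDesign = NULL, seed = 1L) {
  latentKind <- match.arg(latentKind)
  mixing <- match.arg(mixing)
  if (!(snr > 0)) stop("snr must be positive")
  set.seed(as.integer(seed))

  stateLabels <- NULL
  if (latentKind == "arc") {
    param <- seq(0, pi, length.out = T)
    latent <- cbind(cos(param), sin(param))
  } else if (latentKind == "circle") {
    param <- seq(0, 2 * pi, length.out = T + 1L)[seq_len(T)]
    latent <- cbind(cos(param), sin(param))
  } else if (latentKind == "swiss_roll") {
    param <- sort(stats::runif(T, 1.5 * pi, 3.5 * pi))
    h <- stats::runif(T, 0, 6)
    latent <- cbind(param * cos(param), h, param * sin(param))
  } else {
    k <- as.integer(nStates)
    if (is.null(transitionTruth)) {
      transitionTruth <- matrix(0.2 / (k - 1), k, k)
      diag(transitionTruth) <- 0.8
    }
    if (any(abs(rowSums(transitionTruth) - 1) > 1e-10))
      stop("transitionTruth rows must sum to 1")
    stateLabels <- integer(T)
    stateLabels[1L] <- sample.int(k, 1L)
    for (t in 2L:T)
      stateLabels[t] <- sample.int(k, 1L,
                                   prob = transitionTruth[stateLabels[t - 1L], ])
    # planted state means: a regular simplex (all pairs equidistant, edge 8 =
    # 8 x the total within-state spread of ~1: latent jitter 0.5 plus the
    # snr-tied measurement noise in the signal subspace), randomly rotated.
    # Equidistance keeps every cluster-separating eigendirection equally
    # strong; k - 1 > latentDim falls back to rescaled random means.
    if (latentDim >= k - 1L) {
      Xc <- diag(k) - 1 / k
      pts <- (Xc %*% svd(Xc)$v[, seq_len(k - 1L)]) / sqrt(2) * 8
      means <- cbind(pts, matrix(0, k, latentDim - (k - 1L)))
      means <- means %*% randomOrthogonal(latentDim)
    } else {
      means <- matrix(stats::rnorm(k * latentDim, sd = 4), k, latentDim)
      while (min(stats::dist(means)) < 8) means <- means * 1.3
    }
    latent <- means[stateLabels, , drop = FALSE] +
      matrix(stats::rnorm(T * latentDim, sd = 0.5), T, latentDim)
    param <- stateLabels
  }
  ld <- ncol(latent)

  design <- NULL
  if (!is.null(blockDesign)) {
    need <- c("block", "length", "repetitions")
    if (!all(need %in% names(blockDesign)))
      stop("blockDesign needs columns ", paste(need, collapse = ", "))
    # interleave block types: b1 b2 ... bn, repeated
    reps <- unique(blockDesign$repetitions)
    if (length(reps) != 1L)
      stop("invalid spec: all block types must share a repetition count")
    total <- sum(blockDesign$length) * reps
    if (total != T)
      stop("invalid spec: block design fills ", total, " frames, not T = ", T)
    blockCol <- character(0); posCol <- integer(0)
    for (r in seq_len(reps)) for (b in seq_len(nrow(blockDesign))) {
      len <- blockDesign$length[b]
      blockCol <- c(blockCol, rep(as.character(blockDesign$block[b]), len))
      posCol <- c(posCol, seq_len(len) - 1L)
    }
    design <- data.frame(frame = seq_len(T), task = "synthetic",
                         block = blockCol, position = posCol, run = 1L)
  }

  arr <- array(0, dim = c(M, V, T))
  mixList <- vector("list", M)
  for (m in seq_len(M)) {
    W <- if (mixing == "orthogonal") {
      qr.Q(qr(matrix(stats::rnorm(V * ld), V, ld)))
    } else {
      matrix(stats::rnorm(V * ld, sd = 1 / sqrt(ld)), V, ld)
    }
    mixList[[m]] <- W
    signal <- latent %*% t(W)  # T x V
    if (is.finite(snr)) {
      sds <- apply(signal, 2, stats::sd)
      noise <- matrix(stats::rnorm(T * V), T, V)
      if (arCoef != 0) {
        noise <- apply(noise, 2, function(e)
          as.numeric(stats::filter(e, arCoef, method = "recursive")))
        noise <- scale(noise)  # back to unit SD before scaling
      }
      signal <- signal + noise %*% diag(sds / snr, V)
    }
    arr[m, , ] <- t(signal)
  }
  list(tensor = GroupTensor(arr, synchronized = TRUE),
       truth = list(latent = latent, param = param,
                    stateLabels = stateLabels, mixing = mixList,
                    design = design))
}

#' Simulate a temporally rotated scan pair with known alignment
#'
#' Builds one scan X whose region series are zero-mean and unit-norm, and a
#' second scan Y = X O^t where O is a hidden random orthogonal rotation of
#' time that fixes the constant vector (so Y's rows stay zero-mean and
#' unit-norm). [brainSync()] applied to the pair recovers X exactly, making
#' this the exact-recovery fixture for the synchronization step.
#'
#' @param V,T regions and frames (T >= 3).
#' @param seed RNG seed.
#' @param identity use the identity rotation (the pair is then identical).
#' @return list with `x`, `y` (V x T matrices) and `rotation` (T x T).
#' @export
simulateUnsyncPair <- function(V = 30L, T = 80L, seed = 1L,
                               identity = FALSE) {
  set.seed(as.integer(seed))
  X <- normalizeRowsUnit(matrix(stats::rnorm(V * T), V, T))
  if (identity) {
    O <- diag(T)
  } else {
    ones <- rep(1 / sqrt(T), T)
    B <- cbind(ones, qr.Q(qr(cbind(ones, diag(T)[, -1L])))[, -1L])
    R <- randomOrthogonal(T - 1L)
    inner <- rbind(c(1, rep(0, T - 1L)), cbind(0, R))
    O <- B %*% inner %*% t(B)
  }
  list(x = X, y = X %*% t(O), rotation = O)
}
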