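#' Sliding-window MTD dynamic connectivity
#'
#' Multiplication of temporal derivatives: for each pair of nodes the
#' frame-to-frame differences are normalized by each node's derivative SD
#' (population SD over the whole course) and their point-wise product is
#' averaged over a forward window of w + 1 derivative samples starting at each
#' frame, MTD_ij(t) = (1/w) * sum_{k=t}^{t+w} dx_i(k) dx_j(k) / (sd_i sd_j).
#' Windows that would run past the end of the series are dropped; `frameMap`
#' records, for each kept window, the original frame index at which its first
#' temporal derivative is taken.
#'
#' MTD is invariant to positive rescaling of any node's series, and the slice
#' for every window is symmetric by construction.
#'
#' @param series V x T numeric matrix (regions x time), T >= w + 2.
#' @param window window length w >= 1.
#' @return a [DynamicConnectivity-class] with V x V x (T - 1 - w) weights.
#' @export
mtd <- function(series, window) {
  series <- as.matrix(series)
  V <- nrow(series); Tn <- ncol(series)
  w <- as.integer(window)
  if (w < 1L) stop("window must be >= 1")
  if (Tn < w + 2L) stop("need T >= window + 2")
  dx <- series[, -1L, drop = FALSE] - series[, -Tn, drop = FALSE]  # V x (T-1)
  sds <- apply(dx, 1, sdPop)
  if (any(sds == 0)) {
    bad <- rownames(series)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("degenerate node(s) with zero derivative SD: ",
         paste(bad, collapse = ", "))
  }
  z <- dx / sds
  nw <- Tn - 1L - w
  weights <- array(0, dim = c(V, V, nw))
  for (t in seq_len(nw)) {
    slice <- z[, t:(t + w), drop = FALSE]
    weights[, , t] <- tcrossprod(slice) / w
  }
  new("DynamicConnectivity",
      weights = weights,
      windowLength = w,
      frameMap = as.integer(seq_len(nw) + 1L),  # derivative t uses frames t, t+1
      regionIds = if (is.null(rownames(series)))
        sprintf("r%03d", seq_len(V)) else rownames(series))
}

#' Louvain community detection on one connectivity slice
#'
#' Runs the Louvain modularity algorithm on the positive part of a symmetric
#' weight slice (negative weights are removed, the diagonal ignored) with a
#' fixed RNG seed so repeated calls return identical partitions. If the
#' positive graph has no edges a single-module fallback partition is returned
#' with a warning.
#'
#' @param weights V x V symmetric numeric matrix.
#' @param seed RNG seed for the Louvain heuristic.
#' @param resolution Louvain resolution parameter (1 = Newman-Girvan).
#' @return integer vector of module labels, one per node.
#' @export
detectCommunities <- function(weights, seed = 1L, resolution = 1) {
  weights <- as.matrix(weights)
  if (max(abs(weights - t(weights))) > 1e-10)
    stop("weights slice must be symmetric")
  wpos <- pmax(weights, 0)
  diag(wpos) <- 0
  if (all(wpos == 0)) {
    warning("no positive weights; returning a single-module partition")
    return(rep(1L, nrow(weights)))
  }
  g <- igraph::graph_from_adjacency_matrix(wpos, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(as.integer(seed))
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  as.integer(igraph::membership(cl))
}

#' Participation coefficient of every node on one slice
#'
#' For each node i, B_i = 1 - sum_s (k_is / k_i)^2, where k_is is the strength
#' of i's positive connections to nodes in module s and k_i its total positive
#' strength (diagonal excluded). B_i is 0 when all of a node's links stay in
#' one module and approaches 1 - 1/N_M when links spread evenly over all N_M
#' modules; isolated nodes (k_i = 0) get B_i = 0.
#'
#' @param weights V x V symmetric numeric matrix.
#' @param membership integer module label per node (a full partition).
#' @return numeric vector of participation coefficients in [0, 1].
#' @export
participationCoef <- function(weights, membership) {
  weights <- as.matrix(weights)
  V <- nrow(weights)
  if (length(membership) != V)
    stop("membership must cover all nodes")
  wpos <- pmax(weights, 0)
  diag(wpos) <- 0
  ktot <- rowSums(wpos)
  kis <- t(rowsum(t(wpos), group = membership))  # V x modules
  b <- rep(0, V)
  pos <- ktot > 0
  b[pos] <- 1 - rowSums((kis[pos, , drop = FALSE] / ktot[pos])^2)
  b
}

#' Time-resolved communities for a dynamic connectivity object
#'
#' Applies [detectCommunities()] independently to every windowed slice, with
#' a per-frame derived seed so the whole series is reproducible from one seed.
#'
#' @param dc a [DynamicConnectivity-class].
#' @param seed base RNG seed.
#' @param resolution Louvain resolution.
#' @return a [CommunityPartition-class].
#' @export
dynamicCommunities <- function(dc, seed = 1L, resolution = 1) {
  stopifnot(is(dc, "DynamicConnectivity"))
  nw <- dim(dc@weights)[3]
  labels <- matrix(NA_integer_, nrow = dim(dc@weights)[1], ncol = nw)
  for (t in seq_len(nw))
    labels[, t] <- detectCommunities(dc@weights[, , t],
                                     seed = as.integer(seed) + t,
                                     resolution = resolution)
  new("CommunityPartition",
      labels = labels,
      nModules = apply(labels, 2, function(l) length(unique(l))),
      seed = as.integer(seed),
      resolution = resolution)
}

#' Participation-coefficient time series
#'
#' Evaluates node-wise participation coefficients on every connectivity slice
#' under the matching community partition and averages across nodes to get
#' the whole-brain integration index B_T per window.
#'
#' @param dc a [DynamicConnectivity-class].
#' @param partition a [CommunityPartition-class] from [dynamicCommunities()].
#' @return a [ParticipationSeries-class].
#' @export
participationSeries <- function(dc, partition) {
  stopifnot(is(dc, "DynamicConnectivity"), is(partition, "CommunityPartition"))
  nw <- dim(dc@weights)[3]
  if (ncol(partition@labels) != nw)
    stop("partition frame count does not match connectivity")
  node <- vapply(seq_len(nw), function(t)
    participationCoef(dc@weights[, , t], partition@labels[, t]),
    numeric(dim(dc@weights)[1]))
  new("ParticipationSeries",
      nodePC = node,
      globalPC = colMeans(node),
      frameMap = dc@frameMap)
}

#' Group-average whole-brain participation coefficient
#'
#' Elementwise mean of per-subject B_T series; all subjects must share the
#' same window-to-frame map.
#'
#' @param seriesList list of [ParticipationSeries-class] objects.
#' @return a numeric vector (group B_T), with the frame map as an attribute.
#' @export
groupBT <- function(seriesList) {
  stopifnot(length(seriesList) >= 1L)
  fm <- seriesList[[1L]]@frameMap
  for (s in seriesList)
    if (!identical(s@frameMap, fm))
      stop("invalid input: mismatched frame maps across subjects")
  bt <- rowMeans(vapply(seriesList, globalPC, numeric(length(fm))))
  attr(bt, "frameMap") <- fm
  bt
}
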