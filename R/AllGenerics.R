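#' Accessors for manifoldDyn objects
#'
#' Small accessor family: embedding coordinates, eigenvalues, tensor pieces,
#' state labels and Markov quantities. Prefer these over direct slot access.
#'
#' @param object a manifoldDyn S4 object.
#' @return the requested component; see the individual class pages.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("embCoordinates", function(object) standardGeneric("embCoordinates"))

#' @rdname accessors
#' @export
setMethod("embCoordinates", "DiffusionEmbedding", function(object) object@coordinates)

#' @rdname accessors
#' @export
setMethod("embCoordinates", "TwoStepEmbedding", function(object) object@stage2@coordinates)

#' @rdname accessors
#' @export
setMethod("embCoordinates", "LinearTwoStepEmbedding", function(object) object@stage2Scores)

#' @rdname accessors
#' @export
setMethod("embCoordinates", "ExtendedCoordinates", function(object) object@stage2Ext)

#' @rdname accessors
#' @export
setGeneric("embEigenvalues", function(object) standardGeneric("embEigenvalues"))

#' @rdname accessors
#' @export
setMethod("embEigenvalues", "DiffusionEmbedding", function(object) object@eigenvalues)

#' @rdname accessors
#' @export
setGeneric("tensorData", function(object) standardGeneric("tensorData"))

#' @rdname accessors
#' @export
setMethod("tensorData", "GroupTensor", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))

#' @rdname accessors
#' @export
setMethod("subjectIds", "GroupTensor", function(object) object@subjectIds)

#' @rdname accessors
#' @export
setGeneric("isSynchronized", function(object) standardGeneric("isSynchronized"))

#' @rdname accessors
#' @export
setMethod("isSynchronized", "GroupTensor", function(object) object@synchronized)

#' @rdname accessors
#' @export
setGeneric("frameMap", function(object) standardGeneric("frameMap"))

#' @rdname accessors
#' @export
setMethod("frameMap", "DynamicConnectivity", function(object) object@frameMap)

#' @rdname accessors
#' @export
setMethod("frameMap", "ParticipationSeries", function(object) object@frameMap)

#' @rdname accessors
#' @export
setGeneric("globalPC", function(object) standardGeneric("globalPC"))

#' @rdname accessors
#' @export
setMethod("globalPC", "ParticipationSeries", function(object) object@globalPC)

#' @rdname accessors
#' @export
setGeneric("nodePC", function(object) standardGeneric("nodePC"))

#' @rdname accessors
#' @export
setMethod("nodePC", "ParticipationSeries", function(object) object@nodePC)

#' @rdname accessors
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))

#' @rdname accessors
#' @export
setMethod("stateLabels", "StateModel", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("stateCentroids", function(object) standardGeneric("stateCentroids"))

#' @rdname accessors
#' @export
setMethod("stateCentroids", "StateModel", function(object) object@centroids)

#' @rdname accessors
#' @export
setGeneric("chScores", function(object) standardGeneric("chScores"))

#' @rdname accessors
#' @export
setMethod("chScores", "StateModel", function(object) object@chScores)

#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))

#' @rdname accessors
#' @export
setMethod("transitionMatrix", "TransitionModel", function(object) object@transition)

#' @rdname accessors
#' @export
setGeneric("stationaryDist", function(object) standardGeneric("stationaryDist"))

#' @rdname accessors
#' @export
setMethod("stationaryDist", "TransitionModel", function(object) object@stationary)

#' @rdname accessors
#' @export
setGeneric("stateEntropy", function(object) standardGeneric("stateEntropy"))

#' @rdname accessors
#' @export
setMethod("stateEntropy", "TransitionModel", function(object) object@entropy)

#' @rdname accessors
#' @export
setGeneric("dwellCounts", function(object) standardGeneric("dwellCounts"))

#' @rdname accessors
#' @export
setMethod("dwellCounts", "TransitionModel", function(object) object@dwellCounts)

#' @rdname accessors
#' @export
setGeneric("syncRotation", function(object) standardGeneric("syncRotation"))

#' @rdname accessors
#' @export
setMethod("syncRotation", "SyncTransform", function(object) object@rotation)

#' @rdname accessors
#' @export
setGeneric("syncResidual", function(object) standardGeneric("syncResidual"))

#' @rdname accessors
#' @export
setMethod("syncResidual", "SyncTransform", function(object) object@residual)

#' @rdname accessors
#' @export
setGeneric("synchronizedSeries", function(object) standardGeneric("synchronizedSeries"))

#' @rdname accessors
#' @export
setMethod("synchronizedSeries", "SyncTransform", function(object) object@synchronized)

setMethod("show", "GroupTensor", function(object) {
  d <- dim(object@data)
  cat(sprintf("GroupTensor: %d subjects x %d regions x %d frames (%s)\n",
              d[1], d[2], d[3],
              if (object@synchronized) "synchronized" else "unsynchronized"))
})

setMethod("show", "AffinityModel", function(object) {
  cat(sprintf("AffinityModel: %d points, epsilon = %.4g (%s)\n",
              nrow(object@similarity), object@kernelScale, object@strategy))
})

setMethod("show", "DiffusionEmbedding", function(object) {
  cat(sprintf("DiffusionEmbedding: %d points, %d components, t = %d\n",
              nrow(object@coordinates), ncol(object@coordinates),
              object@diffusionTime))
  cat("  eigenvalues:", paste(signif(object@eigenvalues, 4), collapse = " "), "\n")
})

setMethod("show", "TwoStepEmbedding", function(object) {
  cat(sprintf("TwoStepEmbedding: %d subjects, %d frames, d1 = %d, d2 = %d\n",
              length(object@stage1), nrow(object@concatenated),
              object@d1, object@d2))
})

setMethod("show", "DynamicConnectivity", function(object) {
  d <- dim(object@weights)
  cat(sprintf("DynamicConnectivity: %d nodes, %d windows (w = %d)\n",
              d[1], d[3], object@windowLength))
})

setMethod("show", "StateModel", function(object) {
  cat(sprintf("StateModel: k = %d states over %d frames\n",
              object@k, length(object@labels)))
  print(table(state = object@labels))
})

setMethod("show", "TransitionModel", function(object) {
  cat(sprintf("TransitionModel: %d states\n", nrow(object@transition)))
  cat("  stationary:", paste(signif(object@stationary, 3), collapse = " "), "\n")
  cat("  entropy (nats):", paste(signif(object@entropy, 3), collapse = " "), "\n")
})

setMethod("show", "SyncTransform", function(object) {
  cat(sprintf("SyncTransform: %d x %d rotation, residual = %.4g\n",
              nrow(object@rotation), ncol(object@rotation), object@residual))
})
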