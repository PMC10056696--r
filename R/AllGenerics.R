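#' Cluster centroids of a fitted model
#' @param object a [ClusterModel-class].
#' @return k x d numeric matrix.
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @describeIn centroids centroid matrix of a ClusterModel
#' @export
setMethod("centroids", "ClusterModel", function(object) object@centroids)

#' Per-cluster assignment counts
#' @param object a [ClusterModel-class].
#' @return integer vector of length k.
#' @export
setGeneric("clusterCounts", function(object) standardGeneric("clusterCounts"))

#' @describeIn clusterCounts counts of a ClusterModel
#' @export
setMethod("clusterCounts", "ClusterModel", function(object) object@counts)

#' Within-cluster sum of squared distances
#' @param object a [ClusterModel-class].
#' @return single non-negative numeric.
#' @export
setGeneric("inertia", function(object) standardGeneric("inertia"))

#' @describeIn inertia inertia of a ClusterModel
#' @export
setMethod("inertia", "ClusterModel", function(object) object@inertia)

#' Feature matrix of a dataset
#' @param object a [TabularDataset-class].
#' @return n x d numeric matrix.
#' @export
setGeneric("features", function(object) standardGeneric("features"))

#' @describeIn features feature matrix of a TabularDataset
#' @export
setMethod("features", "TabularDataset", function(object) object@features)

#' Binary labels of a dataset
#' @param object a [TabularDataset-class].
#' @param ... unused.
#' @return numeric 0/1 vector, or NULL when unlabelled.
#' @export
setMethod("labels", "TabularDataset", function(object, ...) {
  if (length(object@labels)) object@labels else NULL
})

#' Ensemble member models
#' @param object an [EnsembleModel-class].
#' @return list of [LogRegModel-class].
#' @export
setGeneric("members", function(object) standardGeneric("members"))

#' @describeIn members members of an EnsembleModel
#' @export
setMethod("members", "EnsembleModel", function(object) object@members)

#' Ensemble combination weights
#' @param object an [EnsembleModel-class].
#' @param ... unused.
#' @return numeric weights summing to 1.
#' @export
setMethod("weights", "EnsembleModel", function(object, ...) object@weights)

#' Per-pixel labels of a cluster map
#' @param object a [ClusterMap-class].
#' @return H x W integer matrix, values 0..k-1 (0 = darkest cluster).
#' @export
setGeneric("pixelLabels", function(object) standardGeneric("pixelLabels"))

#' @describeIn pixelLabels label matrix of a ClusterMap
#' @export
setMethod("pixelLabels", "ClusterMap", function(object) object@labels)

#' Cluster mean intensities of a cluster map
#' @param object a [ClusterMap-class].
#' @return numeric vector of k intensities, ascending.
#' @export
setGeneric("clusterMeans", function(object) standardGeneric("clusterMeans"))

#' @describeIn clusterMeans mean intensities of a ClusterMap
#' @export
setMethod("clusterMeans", "ClusterMap", function(object) object@clusterMeans)

setMethod("show", "KMeansConfig", function(object) {
  cat(sprintf(
    "KMeansConfig: k=%d, maxRounds=%d, shiftThreshold=%g, nChunks=%d, seed=%d\n",
    object@k, object@maxRounds, object@shiftThreshold, object@nChunks,
    object@seed
  ))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf(
    "ClusterModel: k=%d clusters in %d dims, n=%d points, inertia=%.6g, %d round(s)\n",
    nrow(object@centroids), ncol(object@centroids), sum(object@counts),
    object@inertia, object@roundsRun
  ))
})

setMethod("show", "TabularDataset", function(object) {
  cat(sprintf(
    "TabularDataset: %d x %d (%s; %d missing cells)\n",
    nrow(object@features), ncol(object@features),
    if (length(object@labels)) "labelled" else "unlabelled",
    sum(is.na(object@features))
  ))
})

setMethod("show", "LogRegModel", function(object) {
  cat(sprintf(
    "LogRegModel: d=%d, bias=%.4g, alpha=%g, %d iteration(s), logLik=%.6g\n",
    length(object@weights), object@bias, object@alpha, object@iterations,
    object@finalLogLik
  ))
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf(
    "EnsembleModel: %d member(s), metric=%s, weights=(%s)\n",
    length(object@members), object@weightMetric,
    paste(sprintf("%.3f", object@weights), collapse = ", ")
  ))
})

setMethod("show", "ClusterMap", function(object) {
  cat(sprintf(
    "ClusterMap: %d x %d pixels, k=%d, means=(%s)\n",
    nrow(object@labels), ncol(object@labels), object@k,
    paste(sprintf("%.4g", object@clusterMeans), collapse = ", ")
  ))
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: S=%d, imageSide=%g (cell %.4g px), %d anchor(s), %d class(es)\n",
    object@S, object@imageSide, object@imageSide / object@S,
    nrow(object@anchors), object@nClasses
  ))
})
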