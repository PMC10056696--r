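#' @import methods
NULL

#' Configuration for chunked k-means
#'
#' Holds the tunables of the chunked (merge-based) k-means: the cluster count
#' `k`, the round budget, the centroid-shift stopping threshold (in feature
#' units), the number of data chunks processed by independent workers, and the
#' seed governing the shuffle and the initial centroid draw.
#'
#' @slot k integer, number of clusters (>= 1).
#' @slot maxRounds integer, maximum merge rounds (>= 1).
#' @slot shiftThreshold numeric, stop when the maximum centroid displacement
#'   between rounds falls below this value (>= 0).
#' @slot nChunks integer, number of data blocks clustered independently each
#'   round (>= 1).
#' @slot seed integer seed for the shuffle and centroid initialization.
#' @export
setClass("KMeansConfig",
  representation(
    k = "integer",
    maxRounds = "integer",
    shiftThreshold = "numeric",
    nChunks = "integer",
    seed = "integer"
  )
)

setValidity("KMeansConfig", function(object) {
  msg <- character()
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    msg <- c(msg, "k must be a single integer >= 1")
  if (length(object@maxRounds) != 1L || object@maxRounds < 1L)
    msg <- c(msg, "maxRounds must be >= 1")
  if (length(object@shiftThreshold) != 1L || is.na(object@shiftThreshold) ||
      object@shiftThreshold < 0)
    msg <- c(msg, "shiftThreshold must be >= 0")
  if (length(object@nChunks) != 1L || object@nChunks < 1L)
    msg <- c(msg, "nChunks must be >= 1")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Construct a KMeansConfig
#'
#' @param k number of clusters.
#' @param maxRounds maximum number of merge rounds.
#' @param shiftThreshold centroid-shift convergence threshold.
#' @param nChunks number of independent data chunks per round.
#' @param seed integer seed.
#' @return A [KMeansConfig-class] object.
#' @examples
#' KMeansConfig(k = 2, nChunks = 4, seed = 1)
#' @export
KMeansConfig <- function(k, maxRounds = 100L, shiftThreshold = 1e-6,
                         nChunks = 1L, seed = 1L) {
  new("KMeansConfig",
    k = as.integer(k), maxRounds = as.integer(maxRounds),
    shiftThreshold = as.numeric(shiftThreshold),
    nChunks = as.integer(nChunks), seed = as.integer(seed)
  )
}

#' Fitted k-means state
#'
#' The result of [fitParallelKMeans()]: the merged centroids, the per-cluster
#' assignment counts on the training data, the within-cluster sum of squared
#' distances (inertia), the number of merge rounds executed, and the
#' configuration used.
#'
#' @slot centroids k x d numeric matrix of cluster centers.
#' @slot counts integer vector of length k; assignment counts, summing to n.
#' @slot inertia numeric, within-cluster sum of squared Euclidean distances.
#' @slot roundsRun integer, merge rounds executed.
#' @slot config the [KMeansConfig-class] used for fitting.
#' @export
setClass("ClusterModel",
  representation(
    centroids = "matrix",
    counts = "integer",
    inertia = "numeric",
    roundsRun = "integer",
    config = "KMeansConfig"
  )
)

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (nrow(object@centroids) != object@config@k)
    msg <- c(msg, "number of centroids must equal config k")
  if (length(object@counts) != object@config@k)
    msg <- c(msg, "counts must have one entry per cluster")
  if (any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (length(object@inertia) != 1L || object@inertia < 0)
    msg <- c(msg, "inertia must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Tabular dataset with optional binary labels
#'
#' A feature matrix with an explicit missing marker (`NA`), optional 0/1
#' labels, and feature names. The container used throughout the tabular
#' classification pipeline.
#'
#' @slot features n x d numeric matrix; `NA` marks missing entries.
#' @slot labels numeric vector of length n with values in {0, 1}, or length 0
#'   when the dataset is unlabelled.
#' @slot featureNames character vector of d column names.
#' @export
setClass("TabularDataset",
  representation(
    features = "matrix",
    labels = "numeric",
    featureNames = "character"
  )
)

setValidity("TabularDataset", function(object) {
  msg <- character()
  if (!is.numeric(object@features))
    msg <- c(msg, "features must be numeric")
  if (length(object@featureNames) != ncol(object@features))
    msg <- c(msg, "featureNames length must equal feature count")
  if (length(object@labels) &&
      length(object@labels) != nrow(object@features))
    msg <- c(msg, "labels length must equal row count")
  if (length(object@labels) &&
      !all(object@labels %in% c(0, 1)))
    msg <- c(msg, "labels must be 0/1")
  if (length(msg)) msg else TRUE
})

#' Construct a TabularDataset
#'
#' @param features numeric matrix (NA = missing).
#' @param labels optional 0/1 vector.
#' @param featureNames optional column names; defaults to existing colnames or
#'   `V1..Vd`.
#' @return A [TabularDataset-class].
#' @examples
#' TabularDataset(matrix(rnorm(20), 10, 2), labels = rep(0:1, 5))
#' @export
TabularDataset <- function(features, labels = NULL, featureNames = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(featureNames)) {
    featureNames <- colnames(features)
    if (is.null(featureNames))
      featureNames <- paste0("V", seq_len(ncol(features)))
  }
  colnames(features) <- featureNames
  new("TabularDataset",
    features = features,
    labels = if (is.null(labels)) numeric(0) else as.numeric(labels),
    featureNames = featureNames
  )
}

#' Logistic-regression model
#'
#' A plain logistic model f(z) = 1 / (1 + exp(-z)) with
#' z = w0 + w1 x1 + ... + wd xd, fitted by full-batch gradient ascent on the
#' Bernoulli log-likelihood.
#'
#' @slot bias numeric, the intercept w0.
#' @slot weights numeric vector w1..wd.
#' @slot alpha positive learning rate.
#' @slot maxIters iteration budget used at fitting.
#' @slot tol convergence tolerance on the change in mean negative
#'   log-likelihood.
#' @slot finalLogLik log-likelihood at the last iteration.
#' @slot iterations iterations actually run.
#' @export
setClass("LogRegModel",
  representation(
    bias = "numeric",
    weights = "numeric",
    alpha = "numeric",
    maxIters = "integer",
    tol = "numeric",
    finalLogLik = "numeric",
    iterations = "integer"
  )
)

setValidity("LogRegModel", function(object) {
  msg <- character()
  if (!all(is.finite(c(object@bias, object@weights))))
    msg <- c(msg, "bias and weights must be finite")
  if (length(object@alpha) != 1L || object@alpha <= 0)
    msg <- c(msg, "alpha must be positive")
  if (length(msg)) msg else TRUE
})

#' Weighted ensemble of logistic models
#'
#' Member models trained on disjoint chunks of the training data, combined by
#' a convex weighting derived from validation performance and optionally
#' refined by a coordinate perturbation search.
#'
#' @slot members list of [LogRegModel-class] objects.
#' @slot weights non-negative numeric weights summing to 1.
#' @slot weightMetric `"accuracy"` or `"auc"`.
#' @slot refinementLog numeric vector of validation scores at each accepted
#'   refinement step (starting score first).
#' @export
setClass("EnsembleModel",
  representation(
    members = "list",
    weights = "numeric",
    weightMetric = "character",
    refinementLog = "numeric"
  )
)

setValidity("EnsembleModel", function(object) {
  msg <- character()
  if (length(object@members) != length(object@weights))
    msg <- c(msg, "one weight per member required")
  if (any(object@weights < 0))
    msg <- c(msg, "weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-12)
    msg <- c(msg, "weights must sum to 1 (within 1e-12)")
  if (!all(vapply(object@members, is, logical(1), "LogRegModel")))
    msg <- c(msg, "members must all be LogRegModel")
  d <- unique(vapply(object@members, function(m) length(m@weights), integer(1)))
  if (length(d) > 1L)
    msg <- c(msg, "members must share a feature dimension")
  if (length(msg)) msg else TRUE
})

#' Per-pixel cluster map of a grayscale image
#'
#' The output of [clusterPixels()]: 0-based per-pixel cluster labels where
#' cluster 0 is the darkest, plus the mean intensity of each cluster (sorted
#' ascending).
#'
#' @slot labels H x W integer matrix with values in 0..k-1.
#' @slot clusterMeans numeric vector of k cluster mean intensities, ascending.
#' @slot k integer, number of clusters.
#' @export
setClass("ClusterMap",
  representation(
    labels = "matrix",
    clusterMeans = "numeric",
    k = "integer"
  )
)

setValidity("ClusterMap", function(object) {
  msg <- character()
  if (length(object@clusterMeans) != object@k)
    msg <- c(msg, "clusterMeans must have k entries")
  if (any(object@labels < 0L) || any(object@labels >= object@k))
    msg <- c(msg, "labels must lie in 0..k-1")
  if (object@k > 1L && any(diff(object@clusterMeans) < 0))
    msg <- c(msg, "clusterMeans must be sorted ascending")
  if (length(msg)) msg else TRUE
})

#' Detection grid specification
#'
#' Geometry of the S x S prediction grid: the image side in pixels, the anchor
#' (width, height) priors in pixels, and the number of object classes. Cells
#' have side `imageSide / S` (real-valued cell sides are allowed).
#'
#' @slot S integer grid side (>= 1).
#' @slot imageSide numeric image side in pixels.
#' @slot anchors m x 2 numeric matrix of (w, h) anchor priors in pixels.
#' @slot nClasses integer number of classes (>= 1).
#' @export
setClass("GridSpec",
  representation(
    S = "integer",
    imageSide = "numeric",
    anchors = "matrix",
    nClasses = "integer"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (object@S < 1L) msg <- c(msg, "S must be >= 1")
  if (object@imageSide <= 0) msg <- c(msg, "imageSide must be positive")
  if (nrow(object@anchors) < 1L || ncol(object@anchors) != 2L)
    msg <- c(msg, "anchors must be a non-empty m x 2 matrix")
  if (object@nClasses < 1L) msg <- c(msg, "nClasses must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param S grid side.
#' @param imageSide image side in pixels.
#' @param anchors m x 2 matrix of (w, h) anchor priors in pixels; default a
#'   single square anchor of one cell side.
#' @param nClasses number of object classes.
#' @return A [GridSpec-class].
#' @examples
#' GridSpec(S = 7, imageSide = 640, nClasses = 2)
#' @export
GridSpec <- function(S, imageSide, anchors = NULL, nClasses = 2L) {
  if (is.null(anchors)) {
    cell <- imageSide / S
    anchors <- matrix(c(cell, cell), 1, 2)
  }
  anchors <- as.matrix(anchors)
  colnames(anchors) <- c("w", "h")
  new("GridSpec",
    S = as.integer(S), imageSide = as.numeric(imageSide),
    anchors = anchors, nClasses = as.integer(nClasses)
  )
}
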