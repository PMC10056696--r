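#' Mean imputation of missing entries
#'
#' Replaces every missing cell with the mean of the observed cells in the same
#' feature. Observed cells are untouched. A fully-missing column is an error.
#'
#' @param ds a [TabularDataset-class].
#' @return A [TabularDataset-class] with no missing values.
#' @examples
#' ds <- TabularDataset(matrix(c(1, NA, 3, 4, 5, 6), 3, 2))
#' features(imputeMean(ds))
#' @export
imputeMean <- function(ds) {
  stopifnot(is(ds, "TabularDataset"))
  x <- ds@features
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (all(miss))
      stop(sprintf("column %d is fully missing; cannot impute a mean",
                   j))
    if (any(miss)) x[miss, j] <- mean(x[!miss, j])
  }
  initialize(ds, features = x)
}

#' Min-max normalization to the unit interval
#'
#' Maps each feature by (x - min) / (max - min). A constant feature maps to 0.
#' The per-feature min and max are returned so the identical transform can be
#' applied to new data with [applyMinmax()]. Requires complete data (run
#' [imputeMean()] first).
#'
#' @param ds a complete [TabularDataset-class].
#' @return A list with elements `data` (the normalized
#'   [TabularDataset-class]) and `ranges` (data.frame with columns `min`,
#'   `max`, one row per feature).
#' @examples
#' minmaxNormalize(TabularDataset(matrix(c(0, 5, 10), 3, 1)))
#' @export
minmaxNormalize <- function(ds) {
  stopifnot(is(ds, "TabularDataset"))
  x <- ds@features
  if (any(is.na(x)))
    stop("missing values present; impute before normalizing")
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  ranges <- data.frame(min = mins, max = maxs,
                       row.names = ds@featureNames)
  list(data = applyMinmax(ds, ranges), ranges = ranges)
}

#' Apply a recorded min-max transform
#'
#' @param ds a complete [TabularDataset-class].
#' @param ranges the `ranges` element returned by [minmaxNormalize()].
#' @return The transformed [TabularDataset-class].
#' @export
applyMinmax <- function(ds, ranges) {
  stopifnot(is(ds, "TabularDataset"))
  x <- ds@features
  if (any(is.na(x)))
    stop("missing values present; impute before normalizing")
  if (nrow(ranges) != ncol(x))
    stop("ranges must have one row per feature")
  for (j in seq_len(ncol(x))) {
    span <- ranges$max[j] - ranges$min[j]
    x[, j] <- if (span == 0) 0 else (x[, j] - ranges$min[j]) / span
  }
  initialize(ds, features = x)
}

#' Flag outlier rows by distance to their assigned centroid
#'
#' A row is flagged when its Euclidean distance to its assigned centroid
#' exceeds the `q`-quantile of all assigned-centroid distances.
#'
#' @param ds a complete [TabularDataset-class].
#' @param model a [ClusterModel-class] fitted on the same feature space.
#' @param q quantile in (0, 1); default 0.99.
#' @return Logical vector of length n; `TRUE` marks an outlier.
#' @examples
#' ds <- TabularDataset(matrix(rnorm(100), 50, 2))
#' m <- fitParallelKMeans(features(ds), KMeansConfig(k = 2, seed = 1))
#' flagOutliers(ds, m, q = 0.95)
#' @export
flagOutliers <- function(ds, model, q = 0.99) {
  stopifnot(is(ds, "TabularDataset"), is(model, "ClusterModel"))
  if (length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1)
    stop("q must lie strictly between 0 and 1")
  x <- .asFeatureMatrix(ds@features)
  lab <- assignPoints(x, model@centroids)
  d2 <- .sqDistToCentroids(x, model@centroids)
  dist <- sqrt(d2[cbind(seq_len(nrow(x)), lab)])
  dist > stats::quantile(dist, q)
}

#' Augment features with cluster information
#'
#' `mode = "indicators"` appends k one-hot cluster-membership columns;
#' `mode = "centroids"` replaces the features with the k Euclidean distances
#' to the centroids (a k-dimensional embedding of the data);
#' `mode = "both"` appends both the distances and the indicators to the
#' original features.
#'
#' @param ds a complete [TabularDataset-class].
#' @param model a [ClusterModel-class] fitted on the same feature space.
#' @param mode one of `"indicators"`, `"centroids"`, `"both"`.
#' @return An augmented [TabularDataset-class].
#' @export
augmentClusterFeatures <- function(ds, model,
                                   mode = c("indicators", "centroids",
                                            "both")) {
  stopifnot(is(ds, "TabularDataset"), is(model, "ClusterModel"))
  mode <- match.arg(mode)
  x <- .asFeatureMatrix(ds@features)
  k <- nrow(model@centroids)
  lab <- assignPoints(x, model@centroids)
  ind <- matrix(0, nrow(x), k)
  ind[cbind(seq_len(nrow(x)), lab)] <- 1
  colnames(ind) <- paste0("cluster", seq_len(k))
  dist <- sqrt(.sqDistToCentroids(x, model@centroids))
  colnames(dist) <- paste0("distCluster", seq_len(k))
  feats <- switch(mode,
    indicators = cbind(x, ind),
    centroids = dist,
    both = cbind(x, dist, ind)
  )
  TabularDataset(feats, labels = if (length(ds@labels)) ds@labels else NULL)
}

#' Full tabular pre-processing pipeline
#'
#' Runs the standard order: mean imputation, min-max normalization, k-means
#' clustering (k = 2 by default), outlier flagging with optional removal, and
#' cluster-feature augmentation.
#'
#' When outliers are dropped, the min-max scaling is recomputed on the
#' retained rows (a far-field outlier would otherwise define the feature
#' range and squash the informative values into a narrow band, which is
#' precisely what the outlier-removal step exists to prevent); the cluster
#' model is refitted on the rescaled data so its centroids live on the final
#' feature scale.
#'
#' @param ds a [TabularDataset-class].
#' @param k clusters for the pre-processing k-means; default 2.
#' @param nChunks chunks for the k-means; default 1.
#' @param q outlier-distance quantile; default 0.99.
#' @param dropOutliers remove flagged rows (default) or keep them.
#' @param mode cluster-feature mode passed to [augmentClusterFeatures()].
#' @param seed integer seed for the clustering.
#' @return A list with elements `data` (processed [TabularDataset-class]),
#'   `model` (the [ClusterModel-class] on the final feature scale), `ranges`
#'   (the min-max record to apply to new data) and `outliers` (logical mask
#'   on the imputed data, pre-removal).
#' @export
preprocessTabular <- function(ds, k = 2L, nChunks = 1L, q = 0.99,
                              dropOutliers = TRUE,
                              mode = "indicators", seed = 1L) {
  ds <- imputeMean(ds)
  nm <- minmaxNormalize(ds)
  cfg <- KMeansConfig(k = k, nChunks = nChunks, seed = seed)
  model <- fitParallelKMeans(nm$data@features, cfg)
  out <- flagOutliers(nm$data, model, q = q)
  if (dropOutliers && any(out)) {
    keep <- !out
    ds <- TabularDataset(ds@features[keep, , drop = FALSE],
                         labels = if (length(ds@labels)) ds@labels[keep]
                                  else NULL,
                         featureNames = ds@featureNames)
    nm <- minmaxNormalize(ds)
    model <- fitParallelKMeans(nm$data@features, cfg)
  }
  aug <- augmentClusterFeatures(nm$data, model, mode = mode)
  list(data = aug, model = model, ranges = nm$ranges, outliers = out)
}
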