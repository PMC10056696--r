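.maxIntensity <- function(bitDepth) 2^bitDepth - 1

#' Quantize a grayscale image by intensity k-means
#'
#' Runs one-dimensional k-means over the pixel intensities (spatial position
#' plays no role) and relabels the clusters so that cluster 0 is the darkest.
#' Initial centroids are k distinct intensity values sampled under the seed,
#' so plateau-heavy images cannot produce duplicate starting centroids; when
#' the image has fewer than k distinct intensities, k is reduced with a
#' warning.
#'
#' @param img H x W numeric matrix of intensities.
#' @param k number of intensity clusters; default 5 (the typical number of
#'   gray-scale stages in chest radiographs).
#' @param nChunks chunks for the underlying clustering; default 1.
#' @param maxRounds,shiftThreshold convergence controls, see
#'   [KMeansConfig()].
#' @param seed integer seed.
#' @return A [ClusterMap-class]: 0-based labels (0 = darkest) and the mean
#'   intensity of each cluster, ascending.
#' @examples
#' img <- matrix(rep(c(10, 100, 200), each = 20), 12, 5)
#' clusterPixels(img, k = 3, seed = 0)
#' @export
clusterPixels <- function(img, k = 5L, nChunks = 1L, maxRounds = 100L,
                          shiftThreshold = 1e-6, seed = 1L) {
  img <- as.matrix(img)
  if (!length(img)) stop("image is empty")
  v <- as.numeric(img)
  u <- sort(unique(v))
  if (length(u) < k) {
    warning(sprintf("image has %d distinct intensities; reducing k from %d",
                    length(u), k))
    k <- length(u)
  }
  set.seed(deriveSeed(seed, "pixel-init"))
  init <- matrix(sample(u, k), ncol = 1)
  cfg <- KMeansConfig(k = k, maxRounds = maxRounds,
                      shiftThreshold = shiftThreshold,
                      nChunks = nChunks, seed = seed)
  model <- fitParallelKMeans(matrix(v, ncol = 1), cfg, init = init)
  lab <- predict(model, matrix(v, ncol = 1))
  # darkest-first canonical order, by actual cluster mean intensity
  means <- vapply(seq_len(k), function(j) {
    px <- v[lab == j]
    if (length(px)) mean(px) else model@centroids[j, 1]
  }, numeric(1))
  ord <- order(means)
  relab <- integer(k)
  relab[ord] <- seq_len(k) - 1L
  labels <- matrix(relab[lab], nrow(img), ncol(img))
  new("ClusterMap", labels = labels, clusterMeans = means[ord],
      k = as.integer(k))
}

#' Render the clustered image
#'
#' Replaces each pixel by the mean intensity of its cluster, rounded to the
#' image bit depth; the result has at most k distinct values (a k-level
#' quantization of the input).
#'
#' @param img H x W numeric matrix.
#' @param map the [ClusterMap-class] for `img`.
#' @param bitDepth 8 or 16; controls rounding/clamping of the rendered means.
#' @return H x W numeric matrix with at most k distinct values.
#' @export
renderClustered <- function(img, map, bitDepth = 8L) {
  img <- as.matrix(img)
  if (!all(dim(img) == dim(map@labels)))
    stop("image and cluster map shapes differ")
  vals <- pmin(pmax(round(map@clusterMeans), 0), .maxIntensity(bitDepth))
  matrix(vals[map@labels + 1L], nrow(img), ncol(img))
}

#' Replace outlier pixels within clusters
#'
#' A pixel whose intensity deviates from its cluster's mean by more than
#' `t` cluster standard deviations is replaced by the cluster mean (rounded
#' to the bit depth); all other pixels are untouched. Removes isolated
#' acquisition artefacts (hot/dead pixels) without blurring region
#' boundaries.
#'
#' @param img H x W numeric matrix.
#' @param map the [ClusterMap-class] for `img`.
#' @param t positive deviation multiplier; default 3.
#' @param bitDepth 8 or 16.
#' @return H x W numeric matrix.
#' @export
removeOutlierPixels <- function(img, map, t = 3.0, bitDepth = 8L) {
  img <- as.matrix(img)
  if (!all(dim(img) == dim(map@labels)))
    stop("image and cluster map shapes differ")
  if (length(t) != 1L || !is.finite(t) || t <= 0)
    stop("t must be positive")
  out <- img
  for (j in seq_len(map@k) - 1L) {
    px <- which(map@labels == j)
    if (!length(px)) next
    m <- mean(img[px])
    s <- stats::sd(img[px])
    if (is.na(s)) s <- 0
    bad <- px[abs(img[px] - m) > t * s]
    if (length(bad))
      out[bad] <- pmin(pmax(round(m), 0), .maxIntensity(bitDepth))
  }
  out
}

# corner-aligned 1-D bilinear interpolation weights: output sample i maps to
# source coordinate 1 + (i-1)(n-1)/(m-1), so the first and last samples hit
# the first and last source values exactly
.bilinearWeights <- function(n, m) {
  W <- matrix(0, m, n)
  if (m == 1L) {
    W[1, 1] <- 1
    return(W)
  }
  pos <- 1 + (seq_len(m) - 1) * (n - 1) / (m - 1)
  lo <- pmin(floor(pos), n - ifelse(n > 1, 1, 0))
  lo <- pmax(lo, 1)
  frac <- pos - lo
  for (i in seq_len(m)) {
    W[i, lo[i]] <- W[i, lo[i]] + (1 - frac[i])
    if (lo[i] < n) W[i, lo[i] + 1] <- W[i, lo[i] + 1] + frac[i]
  }
  W
}

#' Resize to a square side and normalize to the unit interval
#'
#' Corner-aligned bilinear resize to `side` x `side`, followed by min-max
#' scaling to \[0, 1\]. A constant image maps to all zeros.
#'
#' @param img H x W numeric matrix.
#' @param side output side in pixels; default 640.
#' @return side x side numeric matrix with values in \[0, 1\].
#' @export
resizeNormalize <- function(img, side = 640L) {
  img <- as.matrix(img)
  if (!length(img)) stop("image is empty")
  if (side < 1L) stop("side must be >= 1")
  Wr <- .bilinearWeights(nrow(img), side)
  Wc <- .bilinearWeights(ncol(img), side)
  out <- Wr %*% img %*% t(Wc)
  rng <- range(out)
  if (rng[1] == rng[2]) return(matrix(0, side, side))
  (out - rng[1]) / (rng[2] - rng[1])
}

#' Per-cluster region statistics
#'
#' For every cluster: pixel area, centroid (row, col), bounding box, mean
#' intensity, intensity variance and bounding-box aspect ratio
#' (width / height). Areas always sum to the pixel count of the image.
#'
#' @param map the [ClusterMap-class].
#' @param img H x W numeric matrix matching the map.
#' @return data.frame with one row per cluster (0-based `cluster` column).
#' @export
extractRegionFeatures <- function(map, img) {
  img <- as.matrix(img)
  if (!all(dim(img) == dim(map@labels)))
    stop("image and cluster map shapes differ")
  rows <- row(img)
  cols <- col(img)
  out <- lapply(seq_len(map@k) - 1L, function(j) {
    px <- which(map@labels == j)
    if (!length(px)) {
      return(data.frame(cluster = j, area = 0L, centroidRow = NA_real_,
                        centroidCol = NA_real_, minRow = NA_integer_,
                        maxRow = NA_integer_, minCol = NA_integer_,
                        maxCol = NA_integer_, meanIntensity = NA_real_,
                        intensityVar = NA_real_, aspectRatio = NA_real_))
    }
    r <- rows[px]; cl <- cols[px]
    v <- stats::var(img[px])
    data.frame(
      cluster = j, area = length(px),
      centroidRow = mean(r), centroidCol = mean(cl),
      minRow = min(r), maxRow = max(r), minCol = min(cl), maxCol = max(cl),
      meanIntensity = mean(img[px]),
      intensityVar = if (is.na(v)) 0 else v,
      aspectRatio = (max(cl) - min(cl) + 1) / (max(r) - min(r) + 1)
    )
  })
  do.call(rbind, out)
}

#' Stack normalized intensity with the pixel-group channel
#'
#' Builds a two-channel representation: channel 1 is the min-max normalized
#' intensity, channel 2 the cluster label scaled to \[0, 1\] (label /
#' (k - 1); all zeros when k = 1). Channel 2 is constant within each cluster
#' region and multiplying it back by (k - 1) reproduces the label map.
#'
#' @param img H x W numeric matrix.
#' @param map the [ClusterMap-class] for `img`.
#' @return H x W x 2 numeric array.
#' @export
augmentPixelGroupChannel <- function(img, map) {
  img <- as.matrix(img)
  if (!all(dim(img) == dim(map@labels)))
    stop("image and cluster map shapes differ")
  rng <- range(img)
  ch1 <- if (rng[1] == rng[2]) matrix(0, nrow(img), ncol(img)) else
    (img - rng[1]) / (rng[2] - rng[1])
  ch2 <- if (map@k == 1L) matrix(0, nrow(img), ncol(img)) else
    map@labels / (map@k - 1)
  array(c(ch1, ch2), dim = c(nrow(img), ncol(img), 2L))
}
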