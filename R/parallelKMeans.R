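#' @importFrom stats predict
NULL

# squared Euclidean distances from every row of `data` to every centroid;
# computed per centroid with the same summation order as a per-point loop so
# that tie-breaking is reproducible against a brute-force scan
.sqDistToCentroids <- function(data, centroids) {
  k <- nrow(centroids)
  d2 <- matrix(0, nrow(data), k)
  for (j in seq_len(k)) {
    d2[, j] <- rowSums(
      (data - matrix(centroids[j, ], nrow(data), ncol(data), byrow = TRUE))^2
    )
  }
  d2
}

# contiguous blocks of sizes differing by at most 1 (first n %% m blocks are
# the larger ones), over an already-permuted index vector
.chunkIndices <- function(idx, nChunks) {
  n <- length(idx)
  base <- n %/% nChunks
  extra <- n %% nChunks
  sizes <- rep(base, nChunks) + c(rep(1L, extra), rep(0L, nChunks - extra))
  split(idx, rep(seq_len(nChunks), times = sizes))
}

.asFeatureMatrix <- function(data) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (any(!is.finite(data)))
    stop("data must be finite and complete (impute missing values first)")
  data
}

#' Draw initial centroids
#'
#' Samples `k` distinct rows of `data` without replacement under the
#' configuration seed. Identical `(data, seed)` always yields identical
#' centroids.
#'
#' @param data n x d numeric matrix, n >= k.
#' @param config a [KMeansConfig-class].
#' @return k x d matrix of initial centroids (rows of `data`).
#' @examples
#' initCentroids(matrix(rnorm(20), 10, 2), KMeansConfig(k = 3, seed = 0))
#' @export
initCentroids <- function(data, config) {
  data <- .asFeatureMatrix(data)
  n <- nrow(data)
  if (n < config@k)
    stop("need at least k rows to initialize k centroids")
  set.seed(config@seed)
  idx <- sample.int(n, config@k)
  data[idx, , drop = FALSE]
}

#' Assign points to their nearest centroid
#'
#' Euclidean nearest-centroid assignment; distance ties are broken in favour
#' of the lowest centroid index.
#'
#' @param data n x d numeric matrix.
#' @param centroids k x d numeric matrix.
#' @return integer vector of n labels in 1..k.
#' @examples
#' assignPoints(matrix(c(0, 10), 2, 1), matrix(c(1, 9), 2, 1))
#' @export
assignPoints <- function(data, centroids) {
  data <- .asFeatureMatrix(data)
  centroids <- as.matrix(centroids)
  if (ncol(data) != ncol(centroids))
    stop("data and centroids must have the same number of columns")
  d2 <- .sqDistToCentroids(data, centroids)
  max.col(-d2, ties.method = "first")
}

#' Recompute centroids as cluster means
#'
#' Centroid j becomes the mean of points labelled j. An empty cluster is
#' re-seeded to the data point farthest from its previous centroid (or, when
#' `prev` is not supplied, farthest from the global data mean).
#'
#' @param data n x d numeric matrix.
#' @param labels integer labels in 1..k.
#' @param k number of clusters.
#' @param prev optional k x d matrix of the previous centroids, used for
#'   empty-cluster re-seeding.
#' @return k x d matrix of updated centroids.
#' @export
updateCentroids <- function(data, labels, k, prev = NULL) {
  data <- .asFeatureMatrix(data)
  if (any(labels < 1L) || any(labels > k))
    stop("labels must lie in 1..k")
  out <- matrix(NA_real_, k, ncol(data))
  for (j in seq_len(k)) {
    rows <- which(labels == j)
    if (length(rows)) {
      out[j, ] <- colMeans(data[rows, , drop = FALSE])
    } else {
      ref <- if (is.null(prev)) colMeans(data) else prev[j, ]
      d2 <- rowSums(
        (data - matrix(ref, nrow(data), ncol(data), byrow = TRUE))^2
      )
      out[j, ] <- data[which.max(d2), ]
    }
  }
  out
}

#' Chunked k-means with centroid-shift convergence
#'
#' Lloyd-style k-means organised as a coordinator/worker loop: the rows are
#' shuffled under the seed and split into `nChunks` contiguous blocks; each
#' round every worker assigns its block to the current global centroids and
#' recomputes local means, and the coordinator merges the local centroids by
#' count-weighted averaging. The loop stops when the maximum Euclidean
#' centroid displacement falls below `shiftThreshold` (or hits an exact fixed
#' point), or after `maxRounds` rounds. Workers are pure functions of
#' (block, global centroids), so the result depends only on `(data, config)`
#' and never on scheduling; with `nChunks = 1` the procedure is exactly
#' sequential Lloyd iteration.
#'
#' @param data n x d numeric matrix, n >= k.
#' @param config a [KMeansConfig-class].
#' @param init optional k x d matrix of initial centroids; by default k data
#'   rows drawn from the seeded stream (after the shuffle draw).
#' @return A [ClusterModel-class] with merged centroids, assignment counts,
#'   inertia and rounds run.
#' @examples
#' x <- rbind(matrix(rnorm(100), 50, 2), matrix(rnorm(100, 5), 50, 2))
#' fitParallelKMeans(x, KMeansConfig(k = 2, nChunks = 4, seed = 1))
#' @export
fitParallelKMeans <- function(data, config, init = NULL) {
  data <- .asFeatureMatrix(data)
  n <- nrow(data)
  if (n == 0L) stop("data must contain at least one row")
  if (n < config@k) stop("need at least k rows")
  nChunks <- min(config@nChunks, n)

  set.seed(config@seed)
  perm <- sample.int(n)
  if (is.null(init)) {
    init <- data[sample.int(n, config@k), , drop = FALSE]
  } else {
    init <- as.matrix(init)
    if (nrow(init) != config@k || ncol(init) != ncol(data))
      stop("init must be a k x d matrix")
  }
  blocks <- .chunkIndices(perm, nChunks)

  global <- init
  roundsRun <- 0L
  for (r in seq_len(config@maxRounds)) {
    localCent <- vector("list", nChunks)
    localCnt <- matrix(0, nChunks, config@k)
    for (w in seq_len(nChunks)) {
      block <- data[blocks[[w]], , drop = FALSE]
      lab <- assignPoints(block, global)
      localCent[[w]] <- updateCentroids(block, lab, config@k, prev = global)
      localCnt[w, ] <- tabulate(lab, config@k)
    }
    merged <- matrix(0, config@k, ncol(data))
    for (j in seq_len(config@k)) {
      tot <- sum(localCnt[, j])
      cj <- matrix(unlist(lapply(localCent, function(m) m[j, ])),
                   nrow = nChunks, byrow = TRUE)
      nz <- which(localCnt[, j] > 0)
      merged[j, ] <- if (length(nz) == 1L) {
        # single contributing worker: take its centroid exactly, so a
        # one-chunk run reproduces sequential Lloyd bit for bit
        cj[nz, ]
      } else if (tot > 0) {
        colSums(cj * localCnt[, j]) / tot
      } else {
        # all workers re-seeded this cluster: average their re-seeds
        colMeans(cj)
      }
    }
    shift <- sqrt(max(rowSums((merged - global)^2)))
    global <- merged
    roundsRun <- r
    if (shift < config@shiftThreshold || shift == 0) break
  }

  lab <- assignPoints(data, global)
  d2 <- .sqDistToCentroids(data, global)
  new("ClusterModel",
    centroids = global,
    counts = tabulate(lab, config@k),
    inertia = sum(d2[cbind(seq_len(n), lab)]),
    roundsRun = roundsRun,
    config = config
  )
}

#' @describeIn fitParallelKMeans nearest-centroid labels for new points, by
#'   the same assignment rule used during fitting.
#' @param object a fitted [ClusterModel-class].
#' @param newdata points to label (n x d matrix).
#' @export
setMethod("predict", "ClusterModel", function(object, newdata) {
  assignPoints(newdata, object@centroids)
})
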