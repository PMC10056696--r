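# Independent reference implementations used to cross-check the package.
# These deliberately use naive per-point loops, not the package's code paths.

# nearest-centroid labels by exhaustive distance scan
scanAssign <- function(data, centroids) {
  vapply(seq_len(nrow(data)), function(i) {
    d2 <- vapply(seq_len(nrow(centroids)), function(j) {
      sum((data[i, ] - centroids[j, ])^2)
    }, numeric(1))
    which.min(d2)  # which.min takes the first minimum: lowest-index tie rule
  }, integer(1))
}

# textbook sequential Lloyd iteration matching the fit contract: seeded
# shuffle draw (to align the RNG stream), seeded init draw, assign/update
# rounds with count-weighted means, farthest-point re-seeding, and the
# shift-threshold stop
lloydOracle <- function(data, k, seed, maxRounds = 100, shiftThreshold = 1e-6,
                        init = NULL) {
  n <- nrow(data)
  set.seed(seed)
  invisible(sample.int(n))          # the shuffle draw
  cent <- if (is.null(init)) data[sample.int(n, k), , drop = FALSE] else init
  rounds <- 0
  for (r in seq_len(maxRounds)) {
    lab <- scanAssign(data, cent)
    newCent <- cent
    for (j in seq_len(k)) {
      rows <- which(lab == j)
      if (length(rows)) {
        newCent[j, ] <- colMeans(data[rows, , drop = FALSE])
      } else {
        d2 <- vapply(seq_len(n), function(i) sum((data[i, ] - cent[j, ])^2),
                     numeric(1))
        newCent[j, ] <- data[which.max(d2), ]
      }
    }
    shift <- sqrt(max(vapply(seq_len(k), function(j)
      sum((newCent[j, ] - cent[j, ])^2), numeric(1))))
    cent <- newCent
    rounds <- r
    if (shift < shiftThreshold || shift == 0) break
  }
  lab <- scanAssign(data, cent)
  inert <- sum(vapply(seq_len(n), function(i)
    sum((data[i, ] - cent[lab[i], ])^2), numeric(1)))
  list(centroids = cent, labels = lab, counts = tabulate(lab, k),
       inertia = inert, rounds = rounds)
}

# exhaustive pairwise-suppression NMS: repeatedly take the best remaining
# detection and delete everything it overlaps, using a full IoU matrix
bruteNms <- function(dets, iouThresh, objThresh) {
  kept <- integer(0)
  for (cl in sort(unique(dets$classId))) {
    idx <- which(dets$classId == cl & dets$pobj >= objThresh)
    while (length(idx)) {
      best <- idx[order(-dets$conf[idx], idx)][1]
      kept <- c(kept, best)
      drop <- vapply(idx, function(j) {
        j != best && boxIoU(unlist(dets[best, c("x", "y", "w", "h")]),
                            unlist(dets[j, c("x", "y", "w", "h")])) > iouThresh
      }, logical(1))
      idx <- setdiff(idx[!drop], best)
    }
  }
  out <- dets[sort(kept), , drop = FALSE]
  out[order(-out$conf, sort(kept)), , drop = FALSE]
}

# random detection table for NMS stress tests
randomDetections <- function(n, nClasses = 3, side = 100) {
  data.frame(
    classId = sample.int(nClasses, n, replace = TRUE),
    x = runif(n, 10, side - 10),
    y = runif(n, 10, side - 10),
    w = runif(n, 4, 30),
    h = runif(n, 4, 30),
    pobj = runif(n),
    conf = runif(n)
  )
}

# three well-separated Gaussian clusters in 2-D
threeMixture <- function(n = 600, seed = 1) {
  set.seed(seed + 10000)
  centers <- matrix(c(0, 0, 8, 0, 0, 8), 3, 2, byrow = TRUE)
  comp <- rep(1:3, length.out = n)
  centers[comp, ] + matrix(rnorm(2 * n), n, 2)
}
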