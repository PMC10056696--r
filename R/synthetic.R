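#' Generate a tabular dataset with known structure
#'
#' Draws a Gaussian mixture of `kTrue` unit-variance components whose means
#' are `separation` standard deviations from the origin along distinct axes,
#' attaches Bernoulli labels from a logistic mechanism
#' y ~ Bernoulli(sigmoid(w0 + x.w)), then injects far-field outlier rows and
#' missing cells at the requested rates. Labels are drawn before the
#' injections, so the label mechanism stays purely logistic. Fully
#' reproducible from the seed.
#'
#' @param n rows.
#' @param d feature dimension; default 2.
#' @param kTrue mixture components; default 2.
#' @param separation component-mean distance from the origin, in component
#'   standard deviations; default 2.
#' @param w0 true intercept; default -1.
#' @param w true weight vector of length d; default c(2, -3).
#' @param missingRate fraction of cells set missing; default 0.05.
#' @param outlierRate fraction of rows replaced by far-field points;
#'   default 0.01.
#' @param seed integer seed.
#' @return list with `data` (a labelled [TabularDataset-class]) and `truth`
#'   (component assignments, `w0`, `w`, the missing mask and the outlier row
#'   indices).
#' @examples
#' gt <- genTabular(100, seed = 1)
#' table(labels(gt$data))
#' @export
genTabular <- function(n, d = 2L, kTrue = 2L, separation = 2,
                       w0 = -1, w = c(2, -3), missingRate = 0.05,
                       outlierRate = 0.01, seed = 1L) {
  if (missingRate < 0 || missingRate >= 1 || outlierRate < 0 ||
      outlierRate >= 1)
    stop("rates must lie in [0, 1)")
  if (kTrue < 1L) stop("kTrue must be >= 1")
  if (length(w) != d) stop("w must have length d")
  set.seed(seed)
  # component means: separation * unit axis vectors, cycling through the
  # axes with growing magnitude when kTrue > d
  mu <- matrix(0, kTrue, d)
  for (j in seq_len(kTrue)) {
    ax <- (j - 1L) %% d + 1L
    mu[j, ax] <- separation * (1 + (j - 1L) %/% d)
  }
  comp <- sample.int(kTrue, n, replace = TRUE)
  x <- mu[comp, , drop = FALSE] + matrix(stats::rnorm(n * d), n, d)
  p <- sigmoid(w0 + drop(x %*% w))
  y <- stats::rbinom(n, 1L, p)
  nOut <- round(outlierRate * n)
  outlierIdx <- if (nOut > 0) sort(sample.int(n, nOut)) else integer(0)
  if (nOut > 0) {
    # far-field rows: well beyond the mixture support in every coordinate
    shift <- 10 * max(separation, 1) + 5
    x[outlierIdx, ] <- matrix(stats::rnorm(nOut * d, mean = shift), nOut, d)
  }
  missingMask <- matrix(stats::runif(n * d) < missingRate, n, d)
  # keep at least one observed value per column so imputation stays defined
  for (j in seq_len(d)) {
    if (all(missingMask[, j])) missingMask[1, j] <- FALSE
  }
  x[missingMask] <- NA
  list(
    data = TabularDataset(x, labels = y),
    truth = list(component = comp, w0 = w0, w = w,
                 missingMask = missingMask, outlierIdx = outlierIdx)
  )
}

#' Generate banded grayscale images with elliptical lesions
#'
#' Each image consists of `nBands` horizontal intensity bands at distinct
#' levels plus Gaussian noise; with probability `lesionRate` it carries one
#' to three bright elliptical lesions (brighter than every band, so they
#' form their own intensity cluster) with recorded (x, y, w, h)
#' bounding boxes that contain every lesion pixel. Reproducible from the
#' seed.
#'
#' @param nImages number of images.
#' @param side square image side in pixels (>= 32); default 64.
#' @param nBands number of intensity bands (>= 2); default 5.
#' @param lesionRate probability an image carries lesions; default 0.5.
#' @param lesionSizeRange (min, max) lesion diameter in pixels;
#'   default c(6, 14).
#' @param noiseSd additive Gaussian noise SD in intensity units; default 2.
#' @param bitDepth 8 or 16; default 8.
#' @param seed integer seed.
#' @return list with `images` (list of side x side integer matrices) and
#'   `truth` (per-image `boxes` list, `affected` logical vector, and the
#'   band `levels`).
#' @examples
#' gi <- genImages(2, side = 32, noiseSd = 0, seed = 1)
#' length(unique(as.vector(gi$images[[1]])))
#' @export
genImages <- function(nImages, side = 64L, nBands = 5L, lesionRate = 0.5,
                      lesionSizeRange = c(6, 14), noiseSd = 2,
                      bitDepth = 8L, seed = 1L) {
  if (nBands < 2L) stop("nBands must be >= 2")
  if (side < 32L) stop("side must be >= 32")
  if (lesionRate < 0 || lesionRate > 1) stop("lesionRate must be in [0, 1]")
  if (length(lesionSizeRange) != 2L ||
      lesionSizeRange[1] <= 0 || diff(lesionSizeRange) < 0)
    stop("lesionSizeRange must be increasing and positive")
  maxI <- .maxIntensity(bitDepth)
  levels <- round(seq(0.15, 0.8, length.out = nBands) * maxI)
  lesionLevel <- round(0.95 * maxI)
  set.seed(seed)
  bandOf <- rep(seq_len(nBands), times = diff(round(
    seq(0, side, length.out = nBands + 1))))
  images <- vector("list", nImages)
  boxes <- vector("list", nImages)
  affected <- logical(nImages)
  colCenter <- matrix(rep(seq_len(side) - 0.5, each = side), side, side)
  rowCenter <- matrix(rep(seq_len(side) - 0.5, times = side), side, side)
  for (i in seq_len(nImages)) {
    img <- matrix(levels[bandOf], side, side)
    bx <- matrix(numeric(0), 0, 4,
                 dimnames = list(NULL, c("x", "y", "w", "h")))
    if (stats::runif(1) < lesionRate) {
      for (l in seq_len(sample(1:3, 1))) {
        rx <- stats::runif(1, lesionSizeRange[1], lesionSizeRange[2]) / 2
        ry <- stats::runif(1, lesionSizeRange[1], lesionSizeRange[2]) / 2
        cx <- stats::runif(1, rx, side - rx)
        cy <- stats::runif(1, ry, side - ry)
        mask <- ((colCenter - cx) / rx)^2 + ((rowCenter - cy) / ry)^2 <= 1
        img[mask] <- lesionLevel
        bx <- rbind(bx, c(cx, cy, 2 * rx, 2 * ry))
      }
    }
    if (noiseSd > 0) {
      img <- img + matrix(stats::rnorm(side * side, 0, noiseSd), side, side)
      img <- pmin(pmax(round(img), 0), maxI)
    }
    images[[i]] <- img
    boxes[[i]] <- bx
    affected[i] <- nrow(bx) > 0
  }
  list(images = images,
       truth = list(boxes = boxes, affected = affected, levels = levels))
}
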