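#' Grid cell owning a point
#'
#' Cells tile the image in half-open intervals \[(i-1)c, ic) of side
#' c = imageSide / S; a point exactly on an interior boundary belongs to the
#' higher-index cell, and the far image edge belongs to the last cell.
#'
#' @param center numeric (x, y) point in pixels, inside the image.
#' @param spec a [GridSpec-class].
#' @return integer (row, col), 1-based; row indexes y, col indexes x.
#' @examples
#' owningCell(c(0, 0), GridSpec(S = 7, imageSide = 640))
#' @export
owningCell <- function(center, spec) {
  x <- center[1]; y <- center[2]
  if (x < 0 || y < 0 || x > spec@imageSide || y > spec@imageSide)
    stop("point lies outside the image")
  cs <- spec@imageSide / spec@S
  col <- min(floor(x / cs) + 1L, spec@S)
  row <- min(floor(y / cs) + 1L, spec@S)
  c(row = as.integer(row), col = as.integer(col))
}

#' Encode an absolute box into cell-relative coordinates
#'
#' Boxes are (x, y, w, h) with (x, y) the center in absolute pixels. The
#' encoded form is the owning cell plus (bx, by, bw, bh): the center offset
#' within the cell in \[0, 1\] and the width/height measured in cell sides.
#' Note that bw/bh are relative to the CELL side, not the image side, so a
#' box as wide as the image encodes to bw = S.
#'
#' @param box numeric (x, y, w, h), center-based absolute pixels; positive
#'   extent, corners within the image.
#' @param spec a [GridSpec-class].
#' @return list with `cell` (row, col) and `box` (bx, by, bw, bh).
#' @export
encodeBox <- function(box, spec) {
  x <- box[1]; y <- box[2]; w <- box[3]; h <- box[4]
  if (w <= 0 || h <= 0) stop("box must have positive extent")
  if (x - w / 2 < -1e-9 || x + w / 2 > spec@imageSide + 1e-9 ||
      y - h / 2 < -1e-9 || y + h / 2 > spec@imageSide + 1e-9)
    stop("box extends outside the image")
  cell <- owningCell(c(x, y), spec)
  cs <- spec@imageSide / spec@S
  list(
    cell = cell,
    box = c(
      bx = (x - (cell["col"] - 1) * cs) / cs,
      by = (y - (cell["row"] - 1) * cs) / cs,
      bw = w / cs,
      bh = h / cs
    )
  )
}

#' @describeIn encodeBox invert the encoding: absolute (x, y, w, h) from a
#'   cell and its cell-relative box. decode(encode(box)) returns the box to
#'   within 1e-9 pixels.
#' @param cell integer (row, col).
#' @param b numeric (bx, by, bw, bh).
#' @export
decodeBox <- function(cell, b, spec) {
  cs <- spec@imageSide / spec@S
  c(
    x = unname((cell[2] - 1 + b[1]) * cs),
    y = unname((cell[1] - 1 + b[2]) * cs),
    w = unname(b[3] * cs),
    h = unname(b[4] * cs)
  )
}

#' Intersection-over-union of two boxes
#'
#' @param a,b numeric (x, y, w, h) center-based boxes with positive area.
#' @return IoU in \[0, 1\]; 0 for disjoint boxes.
#' @examples
#' boxIoU(c(1, 1, 2, 2), c(2, 1, 2, 2))  # 1/3
#' @export
boxIoU <- function(a, b) {
  if (a[3] <= 0 || a[4] <= 0 || b[3] <= 0 || b[4] <= 0)
    stop("boxes must have positive area")
  ix <- min(a[1] + a[3] / 2, b[1] + b[3] / 2) -
        max(a[1] - a[3] / 2, b[1] - b[3] / 2)
  iy <- min(a[2] + a[4] / 2, b[2] + b[4] / 2) -
        max(a[2] - a[4] / 2, b[2] - b[4] / 2)
  inter <- max(0, ix) * max(0, iy)
  unname(inter / (a[3] * a[4] + b[3] * b[4] - inter))
}

#' Detection confidence
#'
#' The product Pr(class | object) x Pr(object) x IoU(pred, truth), each
#' factor in \[0, 1\].
#'
#' @param pClassGivenObj class probability given an object.
#' @param pObj objectness probability.
#' @param iou overlap with the ground truth.
#' @return their product.
#' @examples
#' detectionConfidence(0.8, 0.9, 0.5)  # 0.36
#' @export
detectionConfidence <- function(pClassGivenObj, pObj, iou) {
  v <- c(pClassGivenObj, pObj, iou)
  if (any(v < 0 | v > 1)) stop("all factors must lie in [0, 1]")
  pClassGivenObj * pObj * iou
}

# vectorized IoU of one box against the rows of a box matrix
.iouMany <- function(b, B) {
  ix <- pmin(b[1] + b[3] / 2, B[, 1] + B[, 3] / 2) -
        pmax(b[1] - b[3] / 2, B[, 1] - B[, 3] / 2)
  iy <- pmin(b[2] + b[4] / 2, B[, 2] + B[, 4] / 2) -
        pmax(b[2] - b[4] / 2, B[, 2] - B[, 4] / 2)
  inter <- pmax(0, ix) * pmax(0, iy)
  inter / (b[3] * b[4] + B[, 3] * B[, 4] - inter)
}

.emptyDetections <- function() {
  data.frame(classId = integer(0), x = numeric(0), y = numeric(0),
             w = numeric(0), h = numeric(0), pobj = numeric(0),
             conf = numeric(0))
}

#' Greedy per-class non-maximum suppression
#'
#' Per class: detections with objectness below `objThresh` are dropped; the
#' remaining are scanned in order of decreasing confidence (ties broken by
#' input position) and each kept detection suppresses later ones whose IoU
#' with it exceeds `iouThresh`. The result is sorted by confidence
#' descending.
#'
#' @param dets data.frame with columns `classId`, `x`, `y`, `w`, `h`,
#'   `pobj`, `conf`.
#' @param iouThresh IoU suppression threshold in \[0, 1\]; default 0.5.
#' @param objThresh objectness threshold in \[0, 1\]; default 0.5 (the low
#'   end of the usual 0.5-0.7 range).
#' @return the surviving subset of `dets`, confidence-sorted.
#' @export
nms <- function(dets, iouThresh = 0.5, objThresh = 0.5) {
  if (iouThresh < 0 || iouThresh > 1 || objThresh < 0 || objThresh > 1)
    stop("thresholds must lie in [0, 1]")
  if (!nrow(dets)) return(.emptyDetections())
  keep <- logical(nrow(dets))
  for (cl in sort(unique(dets$classId))) {
    idx <- which(dets$classId == cl & dets$pobj >= objThresh)
    if (!length(idx)) next
    idx <- idx[order(-dets$conf[idx], idx)]
    boxes <- as.matrix(dets[idx, c("x", "y", "w", "h")])
    alive <- rep(TRUE, length(idx))
    for (i in seq_along(idx)) {
      if (!alive[i]) next
      keep[idx[i]] <- TRUE
      if (i < length(idx)) {
        later <- (i + 1):length(idx)
        hit <- later[.iouMany(boxes[i, ],
                              boxes[later, , drop = FALSE]) > iouThresh]
        alive[hit] <- FALSE
      }
    }
  }
  out <- dets[keep, , drop = FALSE]
  out <- out[order(-out$conf, which(keep)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 1 - IoU of two (w, h) shapes placed at a common center
.shapeDist <- function(wh, anchor) {
  inter <- min(wh[1], anchor[1]) * min(wh[2], anchor[2])
  1 - inter / (wh[1] * wh[2] + anchor[1] * anchor[2] - inter)
}

#' Derive anchor priors from ground-truth box shapes
#'
#' Lloyd-style clustering of (w, h) pairs under the 1 - IoU shape distance
#' (boxes compared at a common center): shapes are assigned to the anchor of
#' highest IoU and each anchor is updated to the mean (w, h) of its members;
#' an empty anchor is re-seeded to the shape farthest from it. Anchors are
#' returned sorted by area ascending.
#'
#' @param gtBoxes matrix with (w, h) in the last two of four columns, or an
#'   m x 2 (w, h) matrix.
#' @param m number of anchors; requires at least m boxes.
#' @param maxIter iteration budget; default 100.
#' @param seed seed for the initial anchor draw.
#' @return m x 2 matrix of (w, h) anchors, area-ascending.
#' @export
anchorsFromBoxes <- function(gtBoxes, m, maxIter = 100L, seed = 1L) {
  gtBoxes <- as.matrix(gtBoxes)
  wh <- if (ncol(gtBoxes) == 4L) gtBoxes[, 3:4, drop = FALSE] else gtBoxes
  if (ncol(wh) != 2L) stop("boxes must supply (w, h) pairs")
  n <- nrow(wh)
  if (n < m) stop("need at least m boxes to derive m anchors")
  if (any(wh <= 0)) stop("box extents must be positive")
  set.seed(seed)
  anchors <- wh[sample.int(n, m), , drop = FALSE]
  lab <- integer(n)
  for (it in seq_len(maxIter)) {
    d <- vapply(seq_len(m), function(j) {
      apply(wh, 1, .shapeDist, anchor = anchors[j, ])
    }, numeric(n))
    d <- matrix(d, nrow = n)
    newLab <- max.col(-d, ties.method = "first")
    newAnchors <- anchors
    for (j in seq_len(m)) {
      rows <- which(newLab == j)
      newAnchors[j, ] <- if (length(rows)) {
        colMeans(wh[rows, , drop = FALSE])
      } else {
        wh[which.max(d[, j]), ]
      }
    }
    done <- all(newLab == lab)
    anchors <- newAnchors
    lab <- newLab
    if (done) break
  }
  anchors <- anchors[order(anchors[, 1] * anchors[, 2]), , drop = FALSE]
  colnames(anchors) <- c("w", "h")
  anchors
}

#' Localization and classification loss of a prediction tensor
#'
#' Each ground-truth box is matched to its owning cell and the anchor prior
#' of highest co-centered IoU. The localization term is the mean squared
#' error over the (bx, by, bw, bh) encodings of the matched pairs; the
#' classification term is the mean cross-entropy of the predicted class
#' probabilities against the one-hot truth (uniform probabilities over C
#' classes give exactly log C per object); the total is their sum.
#'
#' @param predTensor numeric array S x S x A x (5 + C): slot 1 objectness,
#'   slots 2-5 the cell-relative box, slots 6.. the class probabilities.
#' @param truthBoxes n x 4 matrix of (x, y, w, h) absolute-pixel boxes (n >= 1).
#' @param truthClasses integer class ids (1..C) of length n.
#' @param spec a [GridSpec-class].
#' @return list with `locMse`, `clsXent`, `total`.
#' @export
detectionLoss <- function(predTensor, truthBoxes, truthClasses, spec) {
  truthBoxes <- matrix(truthBoxes, ncol = 4)
  if (!nrow(truthBoxes)) stop("truth must contain at least one box")
  A <- nrow(spec@anchors)
  C <- spec@nClasses
  if (!all(dim(predTensor) == c(spec@S, spec@S, A, 5 + C)))
    stop("prediction tensor shape does not match the grid spec")
  se <- 0
  xent <- 0
  eps <- 1e-12
  for (i in seq_len(nrow(truthBoxes))) {
    tb <- truthBoxes[i, ]
    enc <- encodeBox(tb, spec)
    ious <- apply(spec@anchors, 1, function(a)
      boxIoU(c(0, 0, tb[3], tb[4]), c(0, 0, a[1], a[2])))
    a <- which.max(ious)
    pv <- predTensor[enc$cell["row"], enc$cell["col"], a, ]
    se <- se + sum((pv[2:5] - enc$box)^2)
    p <- pv[5 + truthClasses[i]]
    xent <- xent - log(max(p, eps))
  }
  n <- nrow(truthBoxes)
  locMse <- se / (4 * n)
  clsXent <- xent / n
  list(locMse = locMse, clsXent = clsXent, total = locMse + clsXent)
}

#' Decode a prediction tensor into candidate detections
#'
#' @param predTensor numeric array S x S x A x (5 + C); objectness values
#'   must lie in \[0, 1\]. Class slots are normalized to sum to one (uniform
#'   when all zero).
#' @param spec a [GridSpec-class].
#' @return data.frame of candidate detections (one per cell/anchor) with
#'   columns `classId`, `x`, `y`, `w`, `h`, `pobj`, `conf`; confidence is
#'   objectness times the top class probability.
#' @export
decodeTensor <- function(predTensor, spec) {
  A <- nrow(spec@anchors)
  C <- spec@nClasses
  if (length(dim(predTensor)) != 4L ||
      !all(dim(predTensor) == c(spec@S, spec@S, A, 5 + C)))
    stop("prediction tensor shape does not match the grid spec")
  rows <- list()
  for (i in seq_len(spec@S)) for (j in seq_len(spec@S)) for (a in seq_len(A)) {
    pv <- predTensor[i, j, a, ]
    pobj <- pv[1]
    if (pobj < 0 || pobj > 1) stop("objectness must lie in [0, 1]")
    b <- pv[2:5]
    if (b[3] <= 0 || b[4] <= 0) next  # no box predicted at this slot
    probs <- pv[6:(5 + C)]
    s <- sum(probs)
    probs <- if (s > 0) probs / s else rep(1 / C, C)
    cls <- which.max(probs)
    abs <- decodeBox(c(i, j), b, spec)
    rows[[length(rows) + 1L]] <- data.frame(
      classId = cls, x = abs["x"], y = abs["y"], w = abs["w"], h = abs["h"],
      pobj = pobj, conf = pobj * probs[cls]
    )
  }
  if (!length(rows)) return(.emptyDetections())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect lesions and flag an image as affected
#'
#' Runs a backbone (any function mapping an image to an
#' S x S x A x (5 + C) prediction tensor), decodes the tensor, applies
#' per-class non-maximum suppression, and flags the image "affected" when at
#' least one surviving detection carries the disease class id.
#'
#' @param img H x W numeric matrix.
#' @param backbone function(img) returning the prediction tensor.
#' @param spec a [GridSpec-class].
#' @param diseaseClassId class id whose presence flags the image; default 1.
#' @param objThresh,iouThresh thresholds passed to [nms()].
#' @return list with `detections` (post-suppression data.frame), `affected`
#'   (logical) and `flag` (`"affected"` / `"non-affected"`).
#' @export
detectAndFlag <- function(img, backbone, spec, diseaseClassId = 1L,
                          objThresh = 0.5, iouThresh = 0.5) {
  tensor <- backbone(img)
  dets <- decodeTensor(tensor, spec)
  kept <- nms(dets, iouThresh = iouThresh, objThresh = objThresh)
  affected <- any(kept$classId == diseaseClassId)
  list(detections = kept, affected = affected,
       flag = if (affected) "affected" else "non-affected")
}

.cellFeatures <- function(imgNorm, spec) {
  cs <- nrow(imgNorm) / spec@S
  out <- matrix(0, spec@S * spec@S, 3L)
  r <- 0L
  for (i in seq_len(spec@S)) for (j in seq_len(spec@S)) {
    r <- r + 1L
    rr <- max(1L, floor((i - 1) * cs) + 1L):min(nrow(imgNorm), ceiling(i * cs))
    cc <- max(1L, floor((j - 1) * cs) + 1L):min(ncol(imgNorm), ceiling(j * cs))
    block <- imgNorm[rr, cc]
    s <- stats::sd(block)
    out[r, ] <- c(mean(block), max(block), if (is.na(s)) 0 else s)
  }
  out
}

#' Train the tiny reference backbone
#'
#' A deliberately small, fully testable detector head used to exercise the
#' detection geometry end-to-end: per grid cell it computes three intensity
#' summaries (mean, max, sd) of the cell's pixel block, fits a logistic model
#' ([fitLogReg()]) predicting whether the cell overlaps a lesion (a lesion
#' brightens every cell it touches, so overlap -- not center ownership -- is
#' the signal the intensity summaries carry), and
#' predicts every positive cell's box as the average cell-relative encoding
#' of the training lesions. Class probabilities are one-hot on the disease
#' class. This is a reference predictor for synthetic imagery, not a
#' convolutional network.
#'
#' @param images list of H x W matrices (side must equal `spec@imageSide`).
#' @param boxesList list (per image) of n x 4 (x, y, w, h) lesion boxes
#'   (possibly 0-row).
#' @param spec a [GridSpec-class]; the backbone fills anchor slot 1.
#' @param steps training iterations for the logistic cell scorer;
#'   default 200.
#' @param alpha learning rate of the cell scorer; default 20 (the three cell
#'   features live in \[0, 1\] and the positive class is rare, so a large
#'   step is needed for the scorer to reach calibrated probabilities within
#'   the short budget).
#' @param bitDepth intensity depth of the images; default 8.
#' @param seed integer seed.
#' @return function(img) returning an S x S x A x (5 + C) tensor, satisfying
#'   the backbone contract of [detectAndFlag()].
#' @export
trainReferenceBackbone <- function(images, boxesList, spec, steps = 200L,
                                   alpha = 20, bitDepth = 8L, seed = 1L) {
  maxI <- .maxIntensity(bitDepth)
  X <- NULL
  y <- NULL
  encSum <- c(0, 0, 0, 0)
  encN <- 0L
  for (ii in seq_along(images)) {
    img <- images[[ii]] / maxI
    feats <- .cellFeatures(img, spec)
    lab <- rep(0, nrow(feats))
    bx <- boxesList[[ii]]
    if (!is.null(bx) && nrow(bx)) {
      cs <- spec@imageSide / spec@S
      for (b in seq_len(nrow(bx))) {
        enc <- encodeBox(bx[b, ], spec)
        encSum <- encSum + enc$box
        encN <- encN + 1L
        # positive label for every cell the lesion box overlaps
        r <- 0L
        for (i in seq_len(spec@S)) for (j in seq_len(spec@S)) {
          r <- r + 1L
          cellBox <- c((j - 0.5) * cs, (i - 0.5) * cs, cs, cs)
          if (boxIoU(cellBox, bx[b, ]) > 0) lab[r] <- 1
        }
      }
    }
    X <- rbind(X, feats)
    y <- c(y, lab)
  }
  scorer <- fitLogReg(X, y, alpha = alpha, maxIters = steps, seed = seed)
  meanBox <- if (encN) encSum / encN else c(0.5, 0.5, 1, 1)
  A <- nrow(spec@anchors)
  C <- spec@nClasses
  force(spec)
  function(img) {
    feats <- .cellFeatures(as.matrix(img) / maxI, spec)
    p <- predictProba(scorer, feats)
    tensor <- array(0, dim = c(spec@S, spec@S, A, 5 + C))
    r <- 0L
    for (i in seq_len(spec@S)) for (j in seq_len(spec@S)) {
      r <- r + 1L
      tensor[i, j, 1L, 1L] <- p[r]
      tensor[i, j, 1L, 2:5] <- meanBox
      tensor[i, j, 1L, 6L] <- 1  # one-hot on the disease class
    }
    tensor
  }
}
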