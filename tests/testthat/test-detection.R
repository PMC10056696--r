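.spec7 <- GridSpec(S = 7, imageSide = 640, nClasses = 2)

test_that("cell ownership follows the half-open grid convention", {
  expect_equal(unname(owningCell(c(0, 0), .spec7)), c(1L, 1L))

  # a center exactly on an interior boundary joins the higher-index cell
  cs <- 640 / 7
  expect_equal(unname(owningCell(c(cs, 10), .spec7)), c(1L, 2L))
  expect_equal(unname(owningCell(c(10, 3 * cs), .spec7)), c(4L, 1L))
  # the far edge belongs to the last cell
  expect_equal(unname(owningCell(c(640, 640), .spec7)), c(7L, 7L))

  # floor-division oracle on random interior points
  set.seed(81)
  for (i in 1:100) {
    p <- runif(2, 0, 639.99)
    expect_equal(unname(owningCell(p, .spec7)),
                 c(floor(p[2] / cs) + 1, floor(p[1] / cs) + 1))
  }

  expect_error(owningCell(c(-1, 5), .spec7), "outside")
})

test_that("box encoding is cell-relative and exactly invertible", {
  cs <- 640 / 7
  # a box centered in a cell with extent equal to the cell side
  b <- c(2.5 * cs, 4.5 * cs, cs, cs)
  enc <- encodeBox(b, .spec7)
  expect_equal(unname(enc$cell), c(5L, 3L))
  expect_equal(unname(enc$box), c(0.5, 0.5, 1, 1))

  # the full-image box under a one-cell grid
  s1 <- GridSpec(S = 1, imageSide = 640, nClasses = 1)
  encF <- encodeBox(c(320, 320, 640, 640), s1)
  expect_equal(unname(encF$box), c(0.5, 0.5, 1, 1))

  # round-trip identity on random boxes
  set.seed(82)
  for (i in 1:200) {
    w <- runif(1, 1, 200); h <- runif(1, 1, 200)
    x <- runif(1, w / 2, 640 - w / 2); y <- runif(1, h / 2, 640 - h / 2)
    enc <- encodeBox(c(x, y, w, h), .spec7)
    expect_lt(max(abs(decodeBox(enc$cell, enc$box, .spec7) -
                      c(x, y, w, h))), 1e-9)
  }

  expect_error(encodeBox(c(10, 10, 0, 5), .spec7), "positive extent")
})

test_that("IoU and confidence follow their closed forms", {
  expect_equal(boxIoU(c(5, 5, 4, 4), c(5, 5, 4, 4)), 1)
  expect_equal(boxIoU(c(0, 0, 2, 2), c(10, 10, 2, 2)), 0)
  # 2x2 boxes offset by 1 in x: intersection 2, union 6
  expect_equal(boxIoU(c(1, 1, 2, 2), c(2, 1, 2, 2)), 1 / 3)
  expect_error(boxIoU(c(0, 0, 0, 2), c(0, 0, 2, 2)), "positive area")

  expect_equal(detectionConfidence(1, 1, 1), 1)
  expect_equal(detectionConfidence(0, 0.9, 0.8), 0)
  expect_equal(detectionConfidence(0.8, 0.9, 0.5), 0.36)
  # monotone in each factor
  expect_lte(detectionConfidence(0.5, 0.7, 0.4),
             detectionConfidence(0.6, 0.7, 0.4))
  expect_error(detectionConfidence(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("greedy NMS equals the exhaustive suppression oracle", {
  # single confident detection passes through untouched
  one <- data.frame(classId = 1L, x = 50, y = 50, w = 10, h = 10,
                    pobj = 0.9, conf = 0.8)
  expect_equal(nms(one), one)

  # duplicate boxes: only the higher-confidence copy survives
  two <- rbind(one, transform(one, conf = 0.6))
  expect_equal(nrow(nms(two)), 1)
  expect_equal(nms(two)$conf, 0.8)

  # empty input
  expect_equal(nrow(nms(one[0, ])), 0)

  # random fixtures against the brute-force oracle
  for (s in 1:5) {
    set.seed(s)
    dets <- randomDetections(200)
    got <- nms(dets, iouThresh = 0.5, objThresh = 0.5)
    ref <- bruteNms(dets, iouThresh = 0.5, objThresh = 0.5)
    rownames(ref) <- NULL
    expect_equal(got, ref)
    # no two same-class survivors overlap beyond the threshold
    for (cl in unique(got$classId)) {
      sub <- got[got$classId == cl, ]
      if (nrow(sub) > 1) {
        for (i in 1:(nrow(sub) - 1)) for (j in (i + 1):nrow(sub)) {
          expect_lte(boxIoU(unlist(sub[i, c("x", "y", "w", "h")]),
                            unlist(sub[j, c("x", "y", "w", "h")])), 0.5)
        }
      }
    }
  }

  expect_error(nms(one, iouThresh = 2), "thresholds")
})

test_that("anchor derivation clusters box shapes by IoU distance", {
  # identical boxes: every anchor equals that shape
  same <- matrix(rep(c(10, 20), 6), 6, 2, byrow = TRUE)
  a1 <- anchorsFromBoxes(same, 2, seed = 1)
  expect_equal(unname(a1), matrix(rep(c(10, 20), 2), 2, 2, byrow = TRUE))

  # two well-separated size groups land near the group means
  set.seed(83)
  small <- cbind(runif(30, 8, 12), runif(30, 8, 12))
  large <- cbind(runif(30, 80, 120), runif(30, 80, 120))
  a2 <- anchorsFromBoxes(rbind(small, large), 2, seed = 0)
  expect_lt(max(abs(a2[1, ] - colMeans(small)) / colMeans(small)), 0.1)
  expect_lt(max(abs(a2[2, ] - colMeans(large)) / colMeans(large)), 0.1)

  # sorted by area ascending
  expect_true(a2[1, 1] * a2[1, 2] <= a2[2, 1] * a2[2, 2])
  expect_error(anchorsFromBoxes(same[1, , drop = FALSE], 2), "at least m")
})

test_that("detection loss matches its closed forms and a loop oracle", {
  spec <- GridSpec(S = 4, imageSide = 64,
                   anchors = matrix(c(8, 8, 20, 20), 2, 2, byrow = TRUE),
                   nClasses = 3)
  truth <- rbind(c(20, 20, 10, 8), c(50, 44, 22, 18))
  cls <- c(1L, 3L)

  # a tensor holding the exact encodings with one-hot classes: zero loss
  perfect <- array(0, dim = c(4, 4, 2, 8))
  for (i in 1:2) {
    enc <- encodeBox(truth[i, ], spec)
    ious <- apply(spec@anchors, 1, function(a)
      boxIoU(c(0, 0, truth[i, 3], truth[i, 4]), c(0, 0, a[1], a[2])))
    a <- which.max(ious)
    perfect[enc$cell["row"], enc$cell["col"], a, 2:5] <- enc$box
    perfect[enc$cell["row"], enc$cell["col"], a, 5 + cls[i]] <- 1
  }
  lp <- detectionLoss(perfect, truth, cls, spec)
  expect_equal(lp$locMse, 0)
  expect_equal(lp$clsXent, 0)

  # uniform class probabilities: cross-entropy log C per object
  uni <- perfect
  uni[, , , 6:8] <- 1 / 3
  expect_equal(detectionLoss(uni, truth, cls, spec)$clsXent, log(3))

  # random tensor against an explicit summation oracle
  set.seed(84)
  rnd <- array(runif(4 * 4 * 2 * 8), dim = c(4, 4, 2, 8))
  got <- detectionLoss(rnd, truth, cls, spec)
  se <- 0; xe <- 0
  for (i in 1:2) {
    enc <- encodeBox(truth[i, ], spec)
    ious <- apply(spec@anchors, 1, function(a)
      boxIoU(c(0, 0, truth[i, 3], truth[i, 4]), c(0, 0, a[1], a[2])))
    a <- which.max(ious)
    pv <- rnd[enc$cell["row"], enc$cell["col"], a, ]
    se <- se + sum((pv[2:5] - enc$box)^2)
    xe <- xe - log(pv[5 + cls[i]])
  }
  expect_equal(got$locMse, se / 8)
  expect_equal(got$clsXent, xe / 2)
  expect_equal(got$total, got$locMse + got$clsXent)

  expect_error(detectionLoss(rnd, matrix(numeric(0), 0, 4), integer(0), spec),
               "at least one box")
})

test_that("detect-and-flag decodes, suppresses and labels the image", {
  spec <- GridSpec(S = 8, imageSide = 64,
                   anchors = matrix(c(8, 8), 1, 2), nClasses = 2)
  img <- matrix(0, 64, 64)

  # an all-zero backbone yields no detections and a non-affected flag
  zero <- function(im) array(0, dim = c(8, 8, 1, 7))
  r0 <- detectAndFlag(img, zero, spec)
  expect_equal(nrow(r0$detections), 0)
  expect_equal(r0$flag, "non-affected")

  # a backbone that hand-encodes one lesion produces exactly that box
  lesion <- c(36, 28, 10, 12)
  oracleBackbone <- function(im) {
    t <- array(0, dim = c(8, 8, 1, 7))
    enc <- encodeBox(lesion, spec)
    t[enc$cell["row"], enc$cell["col"], 1, 1] <- 0.95
    t[enc$cell["row"], enc$cell["col"], 1, 2:5] <- enc$box
    t[enc$cell["row"], enc$cell["col"], 1, 6] <- 1
    t
  }
  r1 <- detectAndFlag(img, oracleBackbone, spec)
  expect_equal(nrow(r1$detections), 1)
  expect_equal(unlist(r1$detections[1, c("x", "y", "w", "h")]),
               c(x = 36, y = 28, w = 10, h = 12))
  expect_equal(r1$flag, "affected")

  # a wrong-shaped backbone is rejected
  bad <- function(im) array(0, dim = c(4, 4, 1, 7))
  expect_error(detectAndFlag(img, bad, spec), "shape")
})

test_that("the reference backbone learns to flag synthetic lesions", {
  spec <- GridSpec(S = 8, imageSide = 64,
                   anchors = matrix(c(8, 8), 1, 2), nClasses = 2)
  tr <- genImages(30, side = 64, lesionRate = 0.5, seed = 100)
  bb <- trainReferenceBackbone(tr$images, tr$truth$boxes, spec,
                               steps = 200, seed = 0)
  te <- genImages(20, side = 64, lesionRate = 0.5, seed = 321)
  pred <- vapply(te$images, function(im)
    detectAndFlag(im, bb, spec)$affected, logical(1))
  expect_gte(mean(pred == te$truth$affected), 0.9)
})
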