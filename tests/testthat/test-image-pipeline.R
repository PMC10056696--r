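# image with five constant intensity plateaus of equal size
.plateauImage <- function(levels = c(10, 60, 110, 160, 210), side = 40) {
  rows <- rep(seq_along(levels), each = side / length(levels))
  matrix(levels[rows], side, side)
}

test_that("pixel clustering recovers plateaus and orders labels darkest-first", {
  img <- .plateauImage()
  map <- clusterPixels(img, k = 5, seed = 0)
  expect_equal(clusterMeans(map), c(10, 60, 110, 160, 210))
  # every plateau is one cluster, labelled by ascending intensity
  expect_equal(pixelLabels(map), (matrix(rep(1:5, each = 8), 40, 40) - 1L))

  # constant image, k = 1
  mono <- clusterPixels(matrix(42, 8, 8), k = 1, seed = 0)
  expect_equal(clusterMeans(mono), 42)
  expect_true(all(pixelLabels(mono) == 0L))

  # k above the number of distinct intensities is reduced with a warning
  expect_warning(m2 <- clusterPixels(matrix(c(0, 255), 4, 4), k = 5, seed = 1),
                 "reducing k")
  expect_equal(m2@k, 2L)

  expect_error(clusterPixels(matrix(numeric(0), 0, 0)), "empty")
})

test_that("pixel clustering equals a sequential Lloyd oracle on intensities", {
  g <- genImages(1, side = 48, noiseSd = 3, lesionRate = 0, seed = 0)
  img <- g$images[[1]]
  map <- clusterPixels(img, k = 5, seed = 0)

  v <- as.numeric(img)
  u <- sort(unique(v))
  set.seed(deriveSeed(0, "pixel-init"))
  init <- matrix(sample(u, 5), ncol = 1)
  ora <- lloydOracle(matrix(v, ncol = 1), 5, seed = 0, maxRounds = 100,
                     shiftThreshold = 1e-6, init = init)
  # same partition after the darkest-first relabelling
  ord <- order(ora$centroids[, 1])
  relab <- integer(5); relab[ord] <- 0:4
  expect_equal(as.integer(pixelLabels(map)), relab[ora$labels])
})

test_that("rendering quantizes to cluster means", {
  img <- .plateauImage()
  map <- clusterPixels(img, k = 5, seed = 0)
  # k equal to the number of distinct values: lossless
  expect_equal(renderClustered(img, map), img)

  # k = 1: constant image at the rounded global mean
  mono <- clusterPixels(img, k = 1, seed = 0)
  r1 <- renderClustered(img, mono)
  expect_true(all(r1 == round(mean(img))))

  # rendered image never has more than k distinct values, and beats random
  # k-level assignments in squared error
  g <- genImages(1, side = 32, noiseSd = 4, lesionRate = 1, seed = 3)
  noisy <- g$images[[1]]
  m5 <- clusterPixels(noisy, k = 5, seed = 1)
  rend <- renderClustered(noisy, m5)
  expect_lte(length(unique(as.vector(rend))), 5)
  sseRend <- sum((noisy - rend)^2)
  set.seed(71)
  for (i in 1:20) {
    lv <- sample(0:255, 5)
    randImg <- matrix(lv[sample.int(5, length(noisy), replace = TRUE)],
                      nrow(noisy), ncol(noisy))
    expect_lte(sseRend, sum((noisy - randImg)^2))
  }

  expect_error(renderClustered(matrix(0, 2, 2), m5), "shapes")
})

test_that("outlier pixels are replaced by their cluster mean", {
  img <- .plateauImage()
  map <- clusterPixels(img, k = 5, seed = 0)
  # already equal to the rendered image: nothing changes
  expect_equal(removeOutlierPixels(img, map, t = 3), img)

  # one hot pixel injected into a flat region is the only replacement
  hot <- img
  hot[3, 7] <- 95
  cleaned <- removeOutlierPixels(hot, map, t = 3)
  expect_equal(cleaned[3, 7], 10)  # back to its plateau's mean
  idx <- (7 - 1) * 40 + 3
  expect_equal(cleaned[-idx], hot[-idx])

  # enormous t: identity
  expect_equal(removeOutlierPixels(hot, map, t = 1e9), hot)
  expect_error(removeOutlierPixels(hot, map, t = 0), "positive")
})

test_that("resize is corner-aligned bilinear with unit normalization", {
  # identity resize of an image spanning the full 8-bit range
  img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  img[1, 1] <- 0; img[10, 10] <- 255
  expect_equal(resizeNormalize(img, side = 10), img / 255)

  # constant image maps to zeros
  expect_equal(resizeNormalize(matrix(7, 5, 5), side = 8),
               matrix(0, 8, 8))

  # 2x2 -> 4x4: corners preserved, interior linear
  m <- matrix(c(0, 40, 80, 120), 2, 2)
  up <- resizeNormalize(m, side = 4)
  ref <- m / 120
  expect_equal(up[1, 1], ref[1, 1])
  expect_equal(up[4, 1], ref[2, 1])
  expect_equal(up[1, 4], ref[1, 2])
  expect_equal(up[4, 4], ref[2, 2])
  # midpoint of the first column interpolates linearly
  expect_equal(up[2, 1], (2 / 3 * 0 + 1 / 3 * 40) / 120)

  expect_error(resizeNormalize(img, side = 0), "side")
})

test_that("region features accumulate exact per-cluster statistics", {
  # single cluster: full area, centroid at the image center
  mono <- clusterPixels(matrix(5, 6, 8), k = 1, seed = 0)
  rf <- extractRegionFeatures(mono, matrix(5, 6, 8))
  expect_equal(rf$area, 48L)
  expect_equal(rf$centroidRow, 3.5)
  expect_equal(rf$centroidCol, 4.5)

  # two half-images (left dark, right bright): boxes are the two halves
  half <- matrix(rep(c(0, 200), each = 24), 8, 6)
  mh <- clusterPixels(half, k = 2, seed = 0)
  rf2 <- extractRegionFeatures(mh, half)
  expect_equal(rf2$minRow, c(1L, 1L))
  expect_equal(rf2$maxRow, c(8L, 8L))
  expect_equal(rf2$minCol, c(1L, 4L))
  expect_equal(rf2$maxCol, c(3L, 6L))

  # random map against a per-pixel accumulation oracle
  set.seed(72)
  img <- matrix(runif(60, 0, 255), 6, 10)
  lab <- matrix(sample(0:2, 60, replace = TRUE), 6, 10)
  means <- sort(vapply(0:2, function(j) mean(img[lab == j]), numeric(1)))
  map <- new("ClusterMap", labels = lab, clusterMeans = means, k = 3L)
  rf3 <- extractRegionFeatures(map, img)
  expect_equal(sum(rf3$area), 60)
  for (j in 0:2) {
    px <- which(lab == j)
    expect_equal(rf3$meanIntensity[j + 1], mean(img[px]))
    expect_equal(rf3$intensityVar[j + 1], var(img[px]))
    expect_equal(rf3$centroidRow[j + 1], mean(row(img)[px]))
  }
})

test_that("the pixel-group channel encodes labels losslessly", {
  img <- .plateauImage(levels = c(20, 120), side = 8)
  map <- clusterPixels(img, k = 2, seed = 0)
  st <- augmentPixelGroupChannel(img, map)
  expect_equal(dim(st), c(8, 8, 2))
  expect_true(all(st[, , 2] %in% c(0, 1)))

  # channel 2 is constant within each cluster and inverts to the label map
  g <- genImages(1, side = 32, noiseSd = 2, lesionRate = 1, seed = 5)
  m5 <- clusterPixels(g$images[[1]], k = 5, seed = 2)
  st5 <- augmentPixelGroupChannel(g$images[[1]], m5)
  expect_equal(round(st5[, , 2] * 4), matrix(as.numeric(pixelLabels(m5)),
                                             32, 32))
  for (j in 0:4) {
    expect_equal(length(unique(st5[, , 2][pixelLabels(m5) == j])), 1L)
  }

  # k = 1 gives an all-zero group channel
  mono <- clusterPixels(matrix(9, 4, 4), k = 1, seed = 0)
  expect_true(all(augmentPixelGroupChannel(matrix(9, 4, 4), mono)[, , 2] == 0))
})

test_that("re-clustering a rendered image reproduces the partition", {
  g <- genImages(1, side = 40, noiseSd = 3, lesionRate = 0, seed = 8)
  map <- clusterPixels(g$images[[1]], k = 5, seed = 4)
  rend <- renderClustered(g$images[[1]], map)
  map2 <- clusterPixels(rend, k = 5, seed = 4)
  expect_equal(pixelLabels(map2), pixelLabels(map))
})
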