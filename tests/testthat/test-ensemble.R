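# a bias-only member that outputs probability p for every input
.constMember <- function(p) {
  new("LogRegModel", bias = log(p / (1 - p)), weights = 0, alpha = 0.1,
      maxIters = 1L, tol = 1e-8, finalLogLik = NA_real_, iterations = 0L)
}

# a 1-D member predicting 1 exactly when x <= cutoff
.cutoffMember <- function(cutoff) {
  new("LogRegModel", bias = 10 * (cutoff + 0.5), weights = -10, alpha = 0.1,
      maxIters = 1L, tol = 1e-8, finalLogLik = NA_real_, iterations = 0L)
}

.ensembleOf <- function(members, w, metric = "accuracy") {
  new("EnsembleModel", members = members, weights = w / sum(w),
      weightMetric = metric, refinementLog = numeric(0))
}

test_that("splitData partitions at 70/30 with seeded stratification", {
  set.seed(61)
  ds <- TabularDataset(matrix(rnorm(200), 100, 2),
                       labels = rep(c(0, 1), 50))
  sp <- splitData(ds, seed = 9)
  nTr <- nrow(features(sp$train))
  nVa <- nrow(features(sp$val))
  nTe <- nrow(features(sp$test))
  expect_equal(nTr + nVa, 70)  # validation is carved from the 70%
  expect_equal(nTe, 30)
  expect_equal(nTr + nVa + nTe, 100)

  # identical seed, identical partition
  sp2 <- splitData(ds, seed = 9)
  expect_identical(features(sp$train), features(sp2$train))
  expect_identical(features(sp$test), features(sp2$test))

  # stratification keeps the 50/50 label ratio within one sample
  poolLabels <- c(labels(sp$train), labels(sp$val))
  expect_lte(abs(sum(poolLabels == 1) - sum(poolLabels == 0)), 1)

  expect_error(splitData(TabularDataset(matrix(0, 5, 1), labels = rep(0, 5))),
               "at least 10")
})

test_that("partitionChunks yields balanced, disjoint, covering blocks", {
  ds <- TabularDataset(matrix(seq_len(10), 10, 1))
  ch <- partitionChunks(ds, 3, seed = 2)
  sizes <- unname(vapply(ch, function(c) nrow(features(c)), integer(1)))
  expect_equal(sort(sizes, decreasing = TRUE), c(4L, 3L, 3L))
  pooled <- sort(unname(unlist(lapply(ch, function(c) features(c)[, 1]))))
  expect_equal(pooled, as.numeric(1:10))  # disjoint and covering

  one <- partitionChunks(ds, 1, seed = 2)
  expect_equal(sort(features(one[[1]])[, 1]), as.numeric(1:10))

  expect_error(partitionChunks(ds, 11, seed = 1), "more chunks")
})

test_that("weights are proportional to validation performance", {
  val <- TabularDataset(matrix(1:10, 10, 1), labels = rep(c(1, 0), each = 5))

  # members engineered to score 0.6, 0.9 and 0.5 validation accuracy
  members <- list(.cutoffMember(1), .cutoffMember(4), .cutoffMember(10))
  w <- computeWeights(members, val, metric = "accuracy")
  expect_equal(w, c(0.3, 0.45, 0.25))

  # two members of equal performance share the weight
  expect_equal(computeWeights(members[c(2, 2)], val), c(0.5, 0.5))

  # weights sum to one and preserve the metric ordering
  set.seed(62)
  g <- genTabular(120, missingRate = 0, seed = 62)
  sp <- splitData(g$data, seed = 1)
  fits <- lapply(partitionChunks(sp$train, 3, seed = 1), function(ch)
    fitLogReg(features(ch), labels(ch), maxIters = 100))
  wr <- computeWeights(fits, sp$val, metric = "auc")
  expect_equal(sum(wr), 1)
  scores <- vapply(fits, function(m)
    aucROC(predictProba(m, features(sp$val)), labels(sp$val)), numeric(1))
  expect_equal(order(wr), order(scores))

  expect_error(computeWeights(fits, sp$val, metric = "rmse"))
})

test_that("combined probabilities follow the weighted-sum rule", {
  # the worked example: weights (0.3, 0.5, 0.2) on member outputs
  # (0.2, 0.6, 0.5) give 0.06 + 0.30 + 0.10 = 0.46
  ens <- .ensembleOf(list(.constMember(0.2), .constMember(0.6),
                          .constMember(0.5)), c(0.3, 0.5, 0.2))
  expect_equal(combinePredict(ens, matrix(0, 1, 1)), 0.46)

  # identical members reproduce the member output exactly
  same <- .ensembleOf(list(.constMember(0.37), .constMember(0.37)),
                      c(0.5, 0.5))
  expect_equal(combinePredict(same, matrix(0, 3, 1)), rep(0.37, 3))

  # convex-combination bound on random members
  set.seed(63)
  ps <- runif(3, 0.05, 0.95)
  mix <- .ensembleOf(lapply(ps, .constMember), runif(3) + 0.1)
  cp <- combinePredict(mix, matrix(0, 1, 1))
  expect_gte(cp, min(ps))
  expect_lte(cp, max(ps))
})

test_that("weight refinement only accepts improvements", {
  val <- TabularDataset(matrix(1:10, 10, 1), labels = rep(c(1, 0), each = 5))
  members <- list(.cutoffMember(1), .cutoffMember(4), .cutoffMember(10))
  ens <- .ensembleOf(members, computeWeights(members, val))

  # zero rounds: weights untouched
  same <- refineWeights(ens, val, maxRounds = 0)
  expect_identical(weights(same), weights(ens))

  # a single member always keeps weight one
  solo <- .ensembleOf(members[2], 1)
  expect_equal(weights(refineWeights(solo, val, maxRounds = 5)), 1)

  # the accepted-score log never decreases, and the strictly better
  # member's weight never shrinks
  ref <- refineWeights(ens, val, maxRounds = 10)
  expect_true(all(diff(ref@refinementLog) >= 0))
  expect_gte(weights(ref)[2], weights(ens)[2])
  expect_equal(sum(weights(ref)), 1)
})

test_that("a one-chunk ensemble degenerates to a single logistic fit", {
  g <- genTabular(300, missingRate = 0, seed = 64)
  res <- fitEnsemble(g$data, nChunks = 1, preprocess = FALSE,
                     refineRounds = 0, maxIters = 200, seed = 7)

  # replicate the pipeline by hand with a single direct fit
  sp <- splitData(g$data, seed = deriveSeed(7, "split"))
  ch <- partitionChunks(sp$train, 1, seed = deriveSeed(7, "chunks"))[[1]]
  single <- fitLogReg(features(ch), labels(ch), maxIters = 200,
                      seed = deriveSeed(7, "member"))
  expect_identical(combinePredict(res$ensemble, features(sp$test)),
                   predictProba(single, features(sp$test)))
})

test_that("the full pipeline is reproducible and well-formed", {
  g <- genTabular(400, seed = 65)
  r1 <- fitEnsemble(g$data, nChunks = 3, maxIters = 150, seed = 3)
  r2 <- fitEnsemble(g$data, nChunks = 3, maxIters = 150, seed = 3)
  expect_identical(r1$report, r2$report)
  expect_equal(sum(r1$report$weights), 1)
  expect_true(all(c("tp", "fp", "tn", "fn", "precision", "recall",
                    "specificity", "f1", "accuracy", "auc") %in%
                  names(r1$report$test)))
  expect_true(all(diff(r1$report$refinementLog) >= 0))
})
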