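.subsetDataset <- function(ds, idx) {
  TabularDataset(ds@features[idx, , drop = FALSE],
                 labels = if (length(ds@labels)) ds@labels[idx] else NULL,
                 featureNames = ds@featureNames)
}

#' Split a dataset into train / validation / test
#'
#' Seeded partition at a 70/30 train/test ratio by default, with the
#' validation set carved out of the training share. With `stratified = TRUE`
#' (the default when labels are present) the split preserves the label ratio
#' to within one sample per class.
#'
#' @param ds a labelled [TabularDataset-class] with at least 10 rows.
#' @param trainFraction fraction of rows in the training share (including
#'   validation); default 0.7.
#' @param valFractionOfTrain fraction of the training share held out for
#'   validation; default 0.2.
#' @param stratified stratify by label; default TRUE.
#' @param seed integer seed.
#' @return List of [TabularDataset-class] objects: `train`, `val`, `test`
#'   (disjoint, covering all rows).
#' @export
splitData <- function(ds, trainFraction = 0.7, valFractionOfTrain = 0.2,
                      stratified = TRUE, seed = 1L) {
  stopifnot(is(ds, "TabularDataset"))
  n <- nrow(ds@features)
  if (n < 10L) stop("need at least 10 rows to split")
  if (trainFraction <= 0 || trainFraction >= 1 ||
      valFractionOfTrain < 0 || valFractionOfTrain >= 1)
    stop("fractions must lie in (0, 1)")
  y <- if (length(ds@labels)) ds@labels else rep(0, n)
  set.seed(seed)
  trainPool <- integer(0)
  groups <- if (stratified) split(seq_len(n), y) else list(seq_len(n))
  for (g in groups) {
    g <- g[sample.int(length(g))]
    nTr <- round(length(g) * trainFraction)
    if (stratified && length(ds@labels) && nTr == 0L)
      stop("a class would be absent from the training split")
    trainPool <- c(trainPool, g[seq_len(nTr)])
  }
  trainPool <- sort(trainPool)
  testIdx <- setdiff(seq_len(n), trainPool)
  nVal <- round(length(trainPool) * valFractionOfTrain)
  valIdx <- sort(trainPool[sample.int(length(trainPool), nVal)])
  trainIdx <- setdiff(trainPool, valIdx)
  list(
    train = .subsetDataset(ds, trainIdx),
    val = .subsetDataset(ds, valIdx),
    test = .subsetDataset(ds, testIdx)
  )
}

#' Partition training data into balanced chunks
#'
#' Seeded shuffle followed by contiguous blocks whose sizes differ by at most
#' one; the chunks are disjoint and cover the input.
#'
#' @param ds a [TabularDataset-class].
#' @param nChunks number of chunks (<= rows).
#' @param seed integer seed for the shuffle.
#' @return List of `nChunks` [TabularDataset-class] objects.
#' @export
partitionChunks <- function(ds, nChunks, seed = 1L) {
  stopifnot(is(ds, "TabularDataset"))
  n <- nrow(ds@features)
  if (nChunks > n) stop("more chunks than rows")
  set.seed(seed)
  blocks <- .chunkIndices(sample.int(n), nChunks)
  lapply(blocks, function(idx) .subsetDataset(ds, idx))
}

.memberMetric <- function(model, val, metric) {
  X <- val@features
  y <- val@labels
  p <- predictProba(model, X)
  if (metric == "accuracy") {
    mean((p >= 0.5) == y)
  } else {
    aucROC(p, y)
  }
}

#' Validation-performance ensemble weights
#'
#' Each member's weight is proportional to its validation metric (accuracy or
#' rank-based AUC), normalized to sum to one. If every member scores zero the
#' weights are uniform.
#'
#' @param memberModels list of fitted [LogRegModel-class] objects.
#' @param val labelled validation [TabularDataset-class].
#' @param metric `"accuracy"` or `"auc"` (AUC requires both classes in the
#'   validation set).
#' @return numeric weights summing to 1.
#' @export
computeWeights <- function(memberModels, val,
                           metric = c("accuracy", "auc")) {
  metric <- match.arg(metric)
  stopifnot(is(val, "TabularDataset"))
  if (!nrow(val@features) || !length(val@labels))
    stop("validation set must be non-empty and labelled")
  scores <- vapply(memberModels, .memberMetric, numeric(1),
                   val = val, metric = metric)
  if (all(scores == 0)) return(rep(1 / length(scores), length(scores)))
  scores / sum(scores)
}

#' Weighted-combination prediction
#'
#' Each member's predicted probabilities are multiplied by its weight and
#' summed: p(x) = sum_i w_i p_i(x), a convex combination.
#'
#' @param ens an [EnsembleModel-class].
#' @param X feature matrix.
#' @return combined probabilities in \[0, 1\].
#' @export
combinePredict <- function(ens, X) {
  stopifnot(is(ens, "EnsembleModel"))
  Xm <- as.matrix(X)
  probs <- vapply(ens@members, function(m) predictProba(m, Xm),
                  numeric(nrow(Xm)))
  probs <- matrix(probs, nrow = nrow(Xm))
  drop(probs %*% ens@weights)
}

#' @describeIn combinePredict combined 0/1 labels at threshold 0.5.
#' @param object an [EnsembleModel-class].
#' @param newdata feature matrix.
#' @param threshold decision threshold; default 0.5.
#' @export
setMethod("predict", "EnsembleModel", function(object, newdata,
                                               threshold = 0.5) {
  as.numeric(combinePredict(object, newdata) >= threshold)
})

#' Refine ensemble weights by coordinate perturbation
#'
#' Deterministic hill climb on the validation metric: each round tries, for
#' every member in turn, scaling its weight by 1.1 and by 0.9 (renormalizing
#' each time) and keeps a perturbation only when the validation metric
#' strictly improves. Stops after a full round with no accepted move, or at
#' `maxRounds`. The accepted-score log never decreases.
#'
#' @param ens an [EnsembleModel-class].
#' @param val labelled validation [TabularDataset-class].
#' @param maxRounds round budget; default 20. `maxRounds = 0` returns the
#'   ensemble unchanged (with the starting score logged).
#' @return The refined [EnsembleModel-class]; `@refinementLog` holds the
#'   starting validation score followed by every accepted score.
#' @export
refineWeights <- function(ens, val, maxRounds = 20L) {
  stopifnot(is(ens, "EnsembleModel"), is(val, "TabularDataset"))
  metric <- ens@weightMetric
  score <- function(w) {
    tmp <- initialize(ens, weights = w)
    p <- combinePredict(tmp, val@features)
    if (metric == "accuracy") mean((p >= 0.5) == val@labels)
    else aucROC(p, val@labels)
  }
  w <- ens@weights
  current <- score(w)
  log <- current
  if (maxRounds >= 1L) {
    for (round in seq_len(maxRounds)) {
      improved <- FALSE
      for (i in seq_along(w)) {
        for (f in c(1.1, 0.9)) {
          cand <- w
          cand[i] <- cand[i] * f
          cand <- cand / sum(cand)
          s <- score(cand)
          if (s > current) {
            w <- cand
            current <- s
            log <- c(log, s)
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
  }
  initialize(ens, weights = w, refinementLog = log)
}

#' Chunked ensemble logistic-regression pipeline
#'
#' The full classification pipeline: optional pre-processing
#' ([preprocessTabular()]), a seeded train/validation/test split, balanced
#' chunking of the training set, one logistic fit per chunk (a pure function
#' of the chunk, hyperparameters and seed, so the result is independent of
#' execution order), validation-weighted combination, weight refinement, and
#' a test-set evaluation.
#'
#' @param ds a labelled [TabularDataset-class].
#' @param nChunks number of training chunks / ensemble members.
#' @param weightMetric `"accuracy"` or `"auc"`.
#' @param preprocess run [preprocessTabular()] first; default TRUE.
#' @param alpha,maxIters,tol hyperparameters passed to [fitLogReg()].
#' @param refineRounds weight-refinement budget; default 20.
#' @param trainFraction,valFractionOfTrain,stratified split parameters, see
#'   [splitData()].
#' @param k,q,dropOutliers,mode pre-processing parameters, see
#'   [preprocessTabular()].
#' @param seed global seed; stage seeds are derived from it with
#'   [deriveSeed()].
#' @return List with elements `ensemble` (the refined
#'   [EnsembleModel-class]) and `report` (per-member validation metrics,
#'   weights, refinement log, and the test-set evaluation of
#'   [evaluateBinary()]).
#' @export
fitEnsemble <- function(ds, nChunks = 4L,
                        weightMetric = c("accuracy", "auc"),
                        preprocess = TRUE,
                        alpha = 0.1, maxIters = 500L, tol = 1e-8,
                        refineRounds = 20L,
                        trainFraction = 0.7, valFractionOfTrain = 0.2,
                        stratified = TRUE,
                        k = 2L, q = 0.99, dropOutliers = TRUE,
                        mode = "indicators", seed = 1L) {
  weightMetric <- match.arg(weightMetric)
  stopifnot(is(ds, "TabularDataset"))
  if (!length(ds@labels)) stop("dataset must be labelled")
  if (preprocess) {
    prep <- preprocessTabular(ds, k = k, q = q, dropOutliers = dropOutliers,
                              mode = mode,
                              seed = deriveSeed(seed, "preprocess"))
    ds <- prep$data
  }
  splits <- splitData(ds, trainFraction = trainFraction,
                      valFractionOfTrain = valFractionOfTrain,
                      stratified = stratified,
                      seed = deriveSeed(seed, "split"))
  chunks <- partitionChunks(splits$train, nChunks,
                            seed = deriveSeed(seed, "chunks"))
  fitted <- lapply(seq_along(chunks), function(i) {
    ch <- chunks[[i]]
    fitLogReg(ch@features, ch@labels, alpha = alpha, maxIters = maxIters,
              tol = tol, seed = deriveSeed(seed, "member") + i - 1L)
  })
  w <- computeWeights(fitted, splits$val, metric = weightMetric)
  memberScores <- vapply(fitted, .memberMetric, numeric(1),
                         val = splits$val, metric = weightMetric)
  ens <- new("EnsembleModel", members = fitted, weights = w,
             weightMetric = weightMetric, refinementLog = numeric(0))
  ens <- refineWeights(ens, splits$val, maxRounds = refineRounds)
  testP <- combinePredict(ens, splits$test@features)
  report <- list(
    nChunks = nChunks,
    weightMetric = weightMetric,
    memberValidation = memberScores,
    weights = ens@weights,
    refinementLog = ens@refinementLog,
    test = evaluateBinary(splits$test@labels, as.numeric(testP >= 0.5),
                          scores = testP)
  )
  list(ensemble = ens, report = report)
}
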