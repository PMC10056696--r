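#' Derive a stage seed from the global seed
#'
#' Stage seeds are the global seed combined with a polynomial hash of the
#' stage name, reduced modulo 2^31 - 1. Adding a new stage therefore never
#' perturbs the randomness of existing stages.
#'
#' @param seed global integer seed.
#' @param stage stage name (character).
#' @return a non-negative integer seed below 2^31.
#' @examples
#' deriveSeed(1, "split")
#' @export
deriveSeed <- function(seed, stage) {
  p <- 2147483647
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% p
  as.integer((abs(as.numeric(seed)) %% p * 31 + h) %% p)
}

#' Read a tabular CSV into a TabularDataset
#'
#' Comma-separated with a header row; empty cells and "NA" mark missing
#' values; a column named `labelColumn` (if present) supplies the 0/1
#' labels.
#'
#' @param path CSV file path.
#' @param labelColumn name of the label column; default `"label"`.
#' @return A [TabularDataset-class].
#' @export
readTabularCSV <- function(path, labelColumn = "label") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, na.strings = c("", "NA"), data.table = FALSE)
  labels <- NULL
  if (labelColumn %in% names(dt)) {
    labels <- dt[[labelColumn]]
    dt[[labelColumn]] <- NULL
  }
  TabularDataset(as.matrix(dt), labels = labels, featureNames = names(dt))
}

#' Write a TabularDataset to CSV
#'
#' Values are written at full round-trip precision; missing cells become
#' empty fields; labels (when present) are written in a `label` column.
#'
#' @param ds a [TabularDataset-class].
#' @param path output path.
#' @param labelColumn label column name; default `"label"`.
#' @return the path, invisibly.
#' @export
writeTabularCSV <- function(ds, path, labelColumn = "label") {
  df <- as.data.frame(ds@features)
  names(df) <- ds@featureNames
  if (length(ds@labels)) df[[labelColumn]] <- ds@labels
  data.table::fwrite(df, path, na = "")
  invisible(path)
}

#' Read an 8- or 16-bit grayscale PNG
#'
#' @param path PNG file path.
#' @return list with `pixels` (H x W integer-valued matrix on the 0..2^depth-1
#'   scale) and `bitDepth`.
#' @export
readGrayPNG <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  a <- png::readPNG(path, info = TRUE)
  depth <- attr(a, "info")$bit.depth
  if (is.null(depth)) depth <- 8L
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  pix <- round(a * .maxIntensity(depth))
  attributes(pix) <- list(dim = dim(pix))
  list(pixels = pix, bitDepth = as.integer(depth))
}

#' Write a grayscale matrix as PNG
#'
#' Pixels on the 0..2^bitDepth-1 scale are rescaled to the unit interval and
#' written as an 8-bit grayscale PNG (the 8-bit round trip is lossless).
#'
#' @param img H x W numeric matrix of intensities.
#' @param path output path.
#' @param bitDepth depth of the intensity scale of `img`; default 8.
#' @return the path, invisibly.
#' @export
writeGrayPNG <- function(img, path, bitDepth = 8L) {
  png::writePNG(pmin(pmax(img / .maxIntensity(bitDepth), 0), 1), path)
  invisible(path)
}

.modelToList <- function(model) {
  if (is(model, "ClusterModel")) {
    list(type = "ClusterModel",
         centroids = unname(apply(model@centroids, 1, c, simplify = FALSE)),
         counts = model@counts, inertia = model@inertia,
         roundsRun = model@roundsRun,
         config = list(k = model@config@k, maxRounds = model@config@maxRounds,
                       shiftThreshold = model@config@shiftThreshold,
                       nChunks = model@config@nChunks,
                       seed = model@config@seed))
  } else if (is(model, "LogRegModel")) {
    list(type = "LogRegModel", bias = model@bias, weights = model@weights,
         alpha = model@alpha, maxIters = model@maxIters, tol = model@tol,
         finalLogLik = model@finalLogLik, iterations = model@iterations)
  } else if (is(model, "EnsembleModel")) {
    list(type = "EnsembleModel",
         members = lapply(model@members, .modelToList),
         weights = model@weights, weightMetric = model@weightMetric,
         refinementLog = model@refinementLog)
  } else stop("unsupported model class")
}

.modelFromList <- function(x) {
  switch(x$type,
    ClusterModel = new("ClusterModel",
      centroids = if (is.list(x$centroids)) {
        do.call(rbind, lapply(x$centroids, as.numeric))
      } else {
        matrix(as.numeric(x$centroids), nrow = length(x$counts))
      },
      counts = as.integer(x$counts), inertia = as.numeric(x$inertia),
      roundsRun = as.integer(x$roundsRun),
      config = KMeansConfig(x$config$k, x$config$maxRounds,
                            x$config$shiftThreshold, x$config$nChunks,
                            x$config$seed)),
    LogRegModel = new("LogRegModel",
      bias = as.numeric(x$bias), weights = as.numeric(x$weights),
      alpha = as.numeric(x$alpha), maxIters = as.integer(x$maxIters),
      tol = as.numeric(x$tol), finalLogLik = as.numeric(x$finalLogLik),
      iterations = as.integer(x$iterations)),
    EnsembleModel = new("EnsembleModel",
      members = lapply(x$members, .modelFromList),
      weights = as.numeric(x$weights) / sum(as.numeric(x$weights)),
      weightMetric = x$weightMetric,
      refinementLog = as.numeric(x$refinementLog)),
    stop("unknown model type in JSON")
  )
}

#' Serialize a model to JSON
#'
#' Supports [ClusterModel-class], [LogRegModel-class] and
#' [EnsembleModel-class]; the inverse is [readModelJSON()].
#'
#' @param model the model object.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeModelJSON <- function(model, path) {
  jsonlite::write_json(.modelToList(model), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeModelJSON
#' @export
readModelJSON <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  .modelFromList(jsonlite::read_json(path, simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE))
}

#' Write detections as JSON records
#'
#' Each detection becomes a record `{image_id, class_id, x, y, w, h, pobj,
#' conf}` with the box in absolute pixels (center-based). Ground truth is
#' accepted in the same dialect by [readDetectionsJSON()].
#'
#' @param dets detection data.frame (see [nms()]).
#' @param path output path.
#' @param imageId identifier stored with each record; default `"image"`.
#' @return the path, invisibly.
#' @export
writeDetectionsJSON <- function(dets, path, imageId = "image") {
  recs <- lapply(seq_len(nrow(dets)), function(i) {
    list(image_id = imageId, class_id = dets$classId[i],
         x = dets$x[i], y = dets$y[i], w = dets$w[i], h = dets$h[i],
         pobj = dets$pobj[i], conf = dets$conf[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDetectionsJSON
#' @export
readDetectionsJSON <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = TRUE)
  if (!length(recs)) return(.emptyDetections())
  data.frame(classId = recs$class_id, x = recs$x, y = recs$y,
             w = recs$w, h = recs$h, pobj = recs$pobj, conf = recs$conf)
}

.configDefaults <- function() {
  list(
    seed = 1L,
    tabular = list(k = 2L, nChunks = 4L, q = 0.99, dropOutliers = TRUE,
                   mode = "indicators", weightMetric = "accuracy",
                   alpha = 0.1, maxIters = 500L, tol = 1e-8,
                   trainFraction = 0.7, valFractionOfTrain = 0.2,
                   refineRounds = 20L),
    image = list(k = 5L, nChunks = 1L, side = 640L, outlierT = 3.0,
                 detectorInput = "clustered"),
    detection = list(S = 7L, nAnchors = 3L, nClasses = 2L,
                     objThresh = 0.5, iouThresh = 0.5, diseaseClassId = 1L)
  )
}

.mergeConfig <- function(defaults, user, path = "") {
  for (key in names(user)) {
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key: %s%s", path, key))
    if (is.list(defaults[[key]])) {
      if (!is.list(user[[key]]))
        stop(sprintf("configuration key %s%s must be a section", path, key))
      defaults[[key]] <- .mergeConfig(defaults[[key]], user[[key]],
                                      paste0(path, key, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a run configuration (YAML or JSON)
#'
#' Unknown keys are rejected; omitted keys take their documented defaults,
#' so every stage seed is materialized after loading. With `path = NULL` the
#' full default configuration is returned.
#'
#' @param path `.yaml`/`.yml` or `.json` file, or NULL for the defaults.
#' @return nested configuration list.
#' @export
loadRunConfig <- function(path = NULL) {
  defaults <- .configDefaults()
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  }
  if (is.null(user)) user <- list()
  .mergeConfig(defaults, user)
}
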