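## Orchestration of the composition/size experiment grid at desk scale:
## simulate -> (train GAN per class) -> generate -> QC -> mix -> split ->
## train classifier -> evaluate, for every declared cell, against one
## shared freshly-seeded test set.

#' Default desk-scale experiment configuration
#'
#' Returns the fully-populated configuration list; pass overrides as a
#' (possibly nested) list or a YAML file path to [runExperiment()]. Toy
#' scale — 16 x 16 strips, hundreds of images, a few epochs — is the
#' default so a full grid runs in minutes on one CPU; full-scale numbers
#' are configuration values, not code constants.
#' @param overrides nested list of overrides.
#' @return configuration list of class `experimentConfig`.
#' @export
experimentConfig <- function(overrides = list()) {
  cfg <- list(
    seed = 1L,
    image = list(size = 16L, noiseSd = 0.02, lightingAmp = 0.15),
    realPerClass = 100L,
    testPerClass = 40L,
    gan = list(steps = 200L, criticSteps = 2L, baseChannels = 16L,
               noiseDim = 32L, batchSize = 16L, learningRate = 2e-4,
               clipValue = 0.05, attention = TRUE),
    ## at 16 x 16 distinct real strips routinely reach SSIM ~0.99 and
    ## Hamming 0, so the toy profile only rejects near-exact duplicates;
    ## the package-level qcThresholds() defaults are for 128 x 128 images
    qc = list(ssimMax = 0.995, hammingMin = 0L, hashBits = 64L,
              prefilter = FALSE),
    classifier = list(epochs = 8L, batchSize = 32L, learningRate = 5e-3),
    grid = list(
      list(name = "real_only", mode = "ratio", fracReal = 1.0, n = 300L),
      list(name = "mixed_50_50", mode = "ratio", fracReal = 0.5,
           n = 300L)))
  grid <- overrides$grid
  overrides$grid <- NULL
  cfg <- modifyList(cfg, overrides)
  if (!is.null(grid)) cfg$grid <- grid   # replace wholesale, never merge
  class(cfg) <- "experimentConfig"
  cfg
}

#' Simulate strips and downscale to the toy training resolution
#'
#' Renders strips at `4 * size` height (the renderer's band geometry is
#' defined on taller-than-wide strips) and bilinearly downscales to a
#' `size x size` square, giving the small training images the GAN and
#' classifier consume.
#' @param nPerClass strips per class.
#' @param seed RNG seed.
#' @param size square side (default 16).
#' @param noiseSd,lightingAmp simulator nuisance parameters.
#' @return a [StripSet-class] of `3 * nPerClass` square images.
#' @export
miniStripSet <- function(nPerClass, seed = 1L, size = 16L,
                         noiseSd = 0.02, lightingAmp = 0.15) {
  ds <- sampleStripSet(nPerClass, seed = seed,
                       profile = list(height = 4L * size, width = 16L,
                                      noiseSd = noiseSd,
                                      lightingAmp = lightingAmp))
  ds@images <- lapply(seq_len(length(ds)), function(i)
    resizeBilinear(getImage(ds, i), size, size))
  ds@meta$testRow <- NULL
  ds@meta$controlRow <- NULL
  ds
}

## stratified subsample of nTotal records (even across classes), seeded
.subsampleStrata <- function(ds, nTotal, seed) {
  labs <- stripLabels(ds)
  classes <- sort(unique(labs))
  per <- .splitCount(nTotal, length(classes))
  idx <- integer(0)
  withSeed(seed, {
    for (k in seq_along(classes)) {
      pool <- which(labs == classes[k])
      if (length(pool) < per[k])
        stop(sprintf("real pool too small for class %s", classes[k]),
             call. = FALSE)
      idx <- c(idx, sort(pool[sample.int(length(pool), per[k])]))
    }
  })
  ds[idx]
}

## train one GAN per class on the given real subset and generate accepted
## synthetic records (memoized on the real record ids + seed)
.synthesizeForCells <- function(realSubset, nSyn, cfg, cellSeed) {
  classes <- sort(unique(stripLabels(realSubset)))
  per <- .splitCount(nSyn, length(classes))
  thr <- qcThresholds(cfg$qc$ssimMax, cfg$qc$hammingMin, cfg$qc$hashBits)
  out <- NULL
  for (k in seq_along(classes)) {
    if (per[k] == 0L) next
    cls <- classes[k]
    sub <- realSubset[stripLabels(realSubset) == cls]
    gseed <- as.integer(childSeed(cellSeed, k) %% 2^31)
    key <- paste0("expgan:", cls, ":", gseed, ":",
                  paste(stripMeta(sub)$id, collapse = ","))
    model <- .cacheGet(key, function() {
      gcfg <- ganConfig(noiseDim = cfg$gan$noiseDim,
                        imageSize = cfg$image$size,
                        baseChannels = cfg$gan$baseChannels,
                        attention = cfg$gan$attention,
                        clipValue = cfg$gan$clipValue,
                        criticSteps = cfg$gan$criticSteps,
                        learningRate = cfg$gan$learningRate,
                        batchSize = cfg$gan$batchSize,
                        steps = cfg$gan$steps, seed = gseed)
      trainGAN(sub, gcfg, monitorEvery = max(1L, gcfg$steps))
    })
    candidates <- NULL
    accepted <- NULL
    tries <- 0L
    while ((is.null(accepted) || length(accepted) < per[k]) &&
           tries < 5L) {
      tries <- tries + 1L
      cand <- generateImages(model, ceiling(per[k] * 1.5),
                             seed = childSeed(gseed, 100L + tries))
      candidates <- if (is.null(candidates)) cand else c(candidates, cand)
      fl <- filterGenerated(candidates, thr,
                            prefilter = isTRUE(cfg$qc$prefilter))
      accepted <- fl$accepted
    }
    if (length(accepted) < per[k])
      stop(sprintf("QC left only %d/%d synthetic images for class %s",
                   length(accepted), per[k], cls), call. = FALSE)
    out <- if (is.null(out)) accepted[seq_len(per[k])]
           else c(out, accepted[seq_len(per[k])])
  }
  out
}

.evalRow <- function(name, n, model, testSet) {
  pr <- predictProba(model, testSet)
  preds <- model$classes[max.col(pr, ties.method = "first")]
  cm <- confusionCounts(preds, stripLabels(testSet),
                        levels = model$classes)
  met <- classMetrics(cm)
  pc <- met$perClass
  row <- data.frame(composition = name, n = n, accuracy = met$accuracy,
                    stringsAsFactors = FALSE)
  for (cl in pc$class) {
    row[[paste0("sen_", cl)]] <- pc$SEN[pc$class == cl]
    row[[paste0("spe_", cl)]] <- pc$SPE[pc$class == cl]
  }
  list(row = row, cm = cm, metrics = met)
}

.trainEval <- function(name, trainSet, testSet, cfg, cellSeed) {
  sp <- holdoutSplit(trainSet, 0.8, seed = childSeed(cellSeed, 7L))
  ccfg <- trainConfig(batchSize = cfg$classifier$batchSize,
                      learningRate = cfg$classifier$learningRate,
                      epochs = cfg$classifier$epochs,
                      inputSize = cfg$image$size,
                      seed = as.integer(childSeed(cellSeed, 8L) %% 2^31))
  model <- trainClassifier(sp$train, sp$validation, ccfg)
  .evalRow(name, length(trainSet), model, testSet)
}

#' Run the experiment grid
#'
#' For every cell of `config$grid` (a named composition: `mode = "ratio"`
#' with `fracReal` and total `n`, or `mode = "counts"` with
#' `counts = c(real, synthetic)`), the pipeline simulates the real pool,
#' trains one GAN per class on the cell's real records, generates and
#' QC-filters synthetic images, mixes, splits 80:20, trains the
#' classifier, and evaluates on one shared freshly-seeded simulated test
#' set. Every stage seed derives from `config$seed`, so a rerun with the
#' same configuration is byte-identical.
#'
#' @param config an [experimentConfig()], a nested override list, or a
#'   YAML file path.
#' @param outDir optional directory for the consolidated CSV
#'   (`results.csv`), a JSON bundle (`results.json`) and per-cell
#'   confusion CSVs.
#' @return list of class `experimentReport`: `results` (one row per
#'   cell: composition, n, accuracy, per-class SEN/SPE), `cells`
#'   (per-cell confusion matrices and metrics), `failures` (named list of
#'   error messages for failed cells), `config`.
#' @export
runExperiment <- function(config = experimentConfig(), outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "experimentConfig"))
    config <- experimentConfig(config)
  seed <- config$seed
  realPool <- miniStripSet(config$realPerClass,
                           seed = childSeed(seed, 1L),
                           size = config$image$size,
                           noiseSd = config$image$noiseSd,
                           lightingAmp = config$image$lightingAmp)
  testSet <- miniStripSet(config$testPerClass,
                          seed = childSeed(seed, 2L),
                          size = config$image$size,
                          noiseSd = config$image$noiseSd,
                          lightingAmp = config$image$lightingAmp)
  rows <- list(); cells <- list(); failures <- list()
  for (ci in seq_along(config$grid)) {
    cell <- config$grid[[ci]]
    cellSeed <- childSeed(seed, 10L + ci)
    res <- tryCatch({
      if (identical(cell$mode, "counts")) {
        nReal <- as.integer(cell$counts[1])
        nSyn <- as.integer(cell$counts[2])
      } else {
        nReal <- as.integer(round(cell$n * cell$fracReal))
        nSyn <- as.integer(cell$n) - nReal
      }
      realSub <- .subsampleStrata(realPool, nReal,
                                  childSeed(cellSeed, 1L))
      trainSet <- if (nSyn > 0L) {
        syn <- .synthesizeForCells(realSub, nSyn, config, cellSeed)
        mixDatasets(realSub, syn, counts = c(nReal, nSyn),
                    seed = childSeed(cellSeed, 3L))
      } else realSub
      .trainEval(cell$name, trainSet, testSet, config, cellSeed)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[cell$name]] <- conditionMessage(res)
    } else {
      rows[[cell$name]] <- res$row
      cells[[cell$name]] <- res[c("cm", "metrics")]
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(results)) rownames(results) <- NULL
  report <- structure(list(results = results, cells = cells,
                           failures = failures, config = config),
                      class = "experimentReport")
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    if (!is.null(results))
      write.csv(results, file.path(outDir, "results.csv"),
                row.names = FALSE)
    jsonlite::write_json(
      list(results = results, failures = failures),
      file.path(outDir, "results.json"), auto_unbox = TRUE, digits = NA)
    for (nm in names(cells))
      write.csv(as.data.frame(cells[[nm]]$cm),
                file.path(outDir, paste0("confusion-", nm, ".csv")))
  }
  report
}

#' @export
print.experimentReport <- function(x, ...) {
  cat("Experiment report\n")
  if (!is.null(x$results)) print(x$results, digits = 3)
  if (length(x$failures))
    cat("failed cells:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

#' Duplicate a StripSet by mirror flips
#'
#' Each requested axis doubles the dataset: the current records plus
#' their flipped copies. Flipping twice along one axis restores the
#' original image bit-exactly.
#' @param x a [StripSet-class].
#' @param axes subset of `c("horizontal", "vertical")`.
#' @return the enlarged [StripSet-class] (`length(x) * 2^length(axes)`).
#' @export
augmentFlips <- function(x, axes = "horizontal") {
  stopifnot(all(axes %in% c("horizontal", "vertical")))
  out <- x
  for (ax in axes) {
    fl <- out
    fl@images <- lapply(seq_len(length(out)), function(i)
      flipImage(getImage(out, i), ax))
    fl@meta$id <- paste0(fl@meta$id, "-", substr(ax, 1, 1), "flip")
    out <- c(out, fl)
  }
  out
}

#' Geometric-augmentation-only baseline (no GAN)
#'
#' Builds a training set of the configured size purely from rotations and
#' flips of a real subset, trains the same classifier, and evaluates it on
#' the same test fixture, producing a row with the exact schema of
#' [runExperiment()] rows — the comparator for over-used geometric
#' augmentation.
#'
#' @param config as in [runExperiment()]; uses
#'   `config$augmentation = list(nReal, n, stepDeg, axes)` with defaults
#'   `nReal = 3 * realPerClass` (the whole pool), `n = NA` (keep all
#'   derived images), `stepDeg = 90`, `axes = "horizontal"`.
#' @return list of class `experimentReport` with the single baseline row.
#' @export
augmentationOnlyBaseline <- function(config = experimentConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "experimentConfig"))
    config <- experimentConfig(config)
  aug <- modifyList(list(nReal = 3L * config$realPerClass,
                         n = NA, stepDeg = 90, axes = "horizontal"),
                    if (is.null(config$augmentation)) list()
                    else config$augmentation)
  seed <- config$seed
  realPool <- miniStripSet(config$realPerClass,
                           seed = childSeed(seed, 1L),
                           size = config$image$size,
                           noiseSd = config$image$noiseSd,
                           lightingAmp = config$image$lightingAmp)
  testSet <- miniStripSet(config$testPerClass,
                          seed = childSeed(seed, 2L),
                          size = config$image$size,
                          noiseSd = config$image$noiseSd,
                          lightingAmp = config$image$lightingAmp)
  cellSeed <- childSeed(seed, 99L)
  realSub <- .subsampleStrata(realPool, as.integer(aug$nReal),
                              childSeed(cellSeed, 1L))
  augmented <- rotationSweep(realSub, stepDeg = aug$stepDeg)
  augmented <- augmentFlips(augmented, aug$axes)
  if (!is.na(aug$n) && length(augmented) > aug$n)
    augmented <- .subsampleStrata(augmented, as.integer(aug$n),
                                  childSeed(cellSeed, 2L))
  res <- .trainEval("augmentation_only", augmented, testSet, config,
                    cellSeed)
  structure(list(results = res$row,
                 cells = list(augmentation_only = res[c("cm", "metrics")]),
                 failures = list(), config = config),
            class = "experimentReport")
}
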