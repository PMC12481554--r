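## Concentration classifier and the evaluation suite: training (Adam +
## cross-entropy), probability prediction, confusion matrices, per-class
## sensitivity/specificity/PPV/NPV, one-vs-rest ROC/AUC, and t-SNE
## embedding of learned features.

#' Classifier training configuration
#'
#' Defaults follow the reference training recipe: batch size 32, Adam at
#' learning rate 1e-4, cross-entropy loss, 100 epochs, 128 x 128 x 3
#' inputs. The tested backbone is `tiny_cnn` (three stride-2 convolution
#' blocks, global average pooling, linear head); the heavyweight backbone
#' names are accepted by the registry but ship without a builtin
#' constructor (see [registerClassifier()]).
#'
#' @param modelName one of `"tiny_cnn"`, `"resnet50"`, `"mobilenet_v2"`,
#'   `"efficientnet_b0"`, or a name you registered.
#' @param batchSize minibatch size (default 32).
#' @param learningRate Adam learning rate (default 1e-4).
#' @param epochs training epochs (default 100).
#' @param inputSize square input side (default 128).
#' @param seed RNG seed.
#' @return validated list of class `trainConfig`.
#' @export
trainConfig <- function(modelName = "tiny_cnn", batchSize = 32L,
                        learningRate = 1e-4, epochs = 100L,
                        inputSize = 128L, seed = 1L) {
  known <- c("tiny_cnn", "resnet50", "mobilenet_v2", "efficientnet_b0")
  if (!modelName %in% c(known, ls(.clfRegistry)))
    stop(sprintf("unknown model '%s'", modelName), call. = FALSE)
  if (batchSize < 1L || epochs < 1L || learningRate <= 0 || inputSize < 8L)
    stop("invalid training configuration", call. = FALSE)
  structure(list(modelName = modelName, batchSize = as.integer(batchSize),
                 learningRate = learningRate, epochs = as.integer(epochs),
                 inputSize = as.integer(inputSize),
                 seed = as.integer(seed)),
            class = "trainConfig")
}

#' Toy classifier profile used by the test suite
#'
#' 16 x 16 inputs, 8 epochs, learning rate 5e-3 — sized so training on a
#' few hundred simulated strips takes seconds on one CPU.
#' @param ... overrides passed to [trainConfig()].
#' @export
toyTrainConfig <- function(...) {
  defaults <- list(inputSize = 16L, epochs = 8L, learningRate = 5e-3)
  do.call(trainConfig, modifyList(defaults, list(...)))
}

.clfRegistry <- new.env(parent = emptyenv())

#' Register a classifier backbone constructor
#'
#' A constructor is `function(inputSize, nClasses, seed)` returning a list
#' with elements `params` (named weight list), `forward(params, x, train)`
#' and `backward(params, cache, dlogits)` following the `tiny_cnn`
#' implementation.
#' @param name backbone name.
#' @param constructor constructor function.
#' @export
registerClassifier <- function(name, constructor) {
  assign(name, constructor, envir = .clfRegistry)
  invisible(name)
}

## builtin: three stride-2 conv blocks -> GAP -> linear head
.tinyCnn <- function(inputSize, nClasses, seed) {
  widths <- c(8L, 16L, 32L)
  params <- withSeed(seed, list(
    c1.W = initConvW(3L, 3L, widths[1]), c1.b = numeric(widths[1]),
    c2.W = initConvW(3L, widths[1], widths[2]), c2.b = numeric(widths[2]),
    c3.W = initConvW(3L, widths[2], widths[3]), c3.b = numeric(widths[3]),
    fc.W = initLinW(widths[3], nClasses), fc.b = numeric(nClasses)))
  forward <- function(p, x, train = FALSE) {
    x <- x - 0.5                               # centre [0,1] pixel inputs
    c1 <- convForward(x, p$c1.W, p$c1.b, 3L, stride = 2L, pad = 1L)
    a1 <- lrelu(c1$out, 0)
    c2 <- convForward(a1, p$c2.W, p$c2.b, 3L, stride = 2L, pad = 1L)
    a2 <- lrelu(c2$out, 0)
    c3 <- convForward(a2, p$c3.W, p$c3.b, 3L, stride = 2L, pad = 1L)
    a3 <- lrelu(c3$out, 0)
    d <- dim(a3)
    feats <- apply(a3, c(1, 4), mean)          # global average pool
    dim(feats) <- c(d[1], d[4])
    logits <- linForward(feats, p$fc.W, p$fc.b)
    if (!train) return(list(logits = logits, features = feats))
    list(logits = logits, features = feats,
         cache = list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3,
                      a3 = a3, feats = feats, spatial = d))
  }
  backward <- function(p, cache, dlogits) {
    g <- list()
    bl <- linBackward(dlogits, cache$feats, p$fc.W)
    g$fc.W <- bl$dW; g$fc.b <- bl$db
    d <- cache$spatial
    ## GAP backward: spread each feature grad uniformly over positions
    da3 <- array(0, dim = d)
    scale <- 1 / (d[2] * d[3])
    for (cc in seq_len(d[4]))
      da3[, , , cc] <- bl$dx[, cc] * scale
    dc3 <- lreluBack(da3, cache$c3$out, 0)
    b3 <- convBackward(dc3, cache$c3, p$c3.W)
    g$c3.W <- b3$dW; g$c3.b <- b3$db
    dc2 <- lreluBack(b3$dx, cache$c2$out, 0)
    b2 <- convBackward(dc2, cache$c2, p$c2.W)
    g$c2.W <- b2$dW; g$c2.b <- b2$db
    dc1 <- lreluBack(b2$dx, cache$c1$out, 0)
    b1 <- convBackward(dc1, cache$c1, p$c1.W)
    g$c1.W <- b1$dW; g$c1.b <- b1$db
    g
  }
  list(params = params, forward = forward, backward = backward)
}

.buildBackbone <- function(cfg, nClasses) {
  if (cfg$modelName == "tiny_cnn")
    return(.tinyCnn(cfg$inputSize, nClasses, cfg$seed))
  if (exists(cfg$modelName, envir = .clfRegistry))
    return(get(cfg$modelName, envir = .clfRegistry)(cfg$inputSize,
                                                    nClasses, cfg$seed))
  stop(sprintf(paste0(
    "backbone '%s' is accepted by the registry but has no builtin ",
    "constructor in this package; register one with registerClassifier()"),
    cfg$modelName), call. = FALSE)
}

.softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train a concentration classifier
#'
#' Minimizes cross-entropy with Adam, recording per-epoch training and
#' validation loss/accuracy; the weights with the best validation accuracy
#' (earliest epoch on ties) are retained. Seed-reproducible.
#'
#' @param train,val [StripSet-class] splits with identical label sets.
#' @param cfg a [trainConfig()].
#' @return list of class `stripClassifier`: `params`, `classes`,
#'   `history` (one row per epoch), `cfg`, `bestEpoch`.
#' @export
trainClassifier <- function(train, val, cfg = trainConfig()) {
  stopifnot(is(train, "StripSet"), is(val, "StripSet"),
            inherits(cfg, "trainConfig"))
  if (!length(train) || !length(val))
    stop("empty split", call. = FALSE)
  classes <- sort(unique(stripLabels(train)))
  if (!setequal(classes, unique(stripLabels(val))))
    stop("train and validation label sets differ", call. = FALSE)
  K <- length(classes)
  Xtr <- stackImages(train); ytr <- match(stripLabels(train), classes)
  Xva <- stackImages(val); yva <- match(stripLabels(val), classes)
  if (dim(Xtr)[2] != cfg$inputSize)
    stop("images do not match cfg$inputSize", call. = FALSE)
  bb <- .buildBackbone(cfg, K)
  p <- bb$params
  state <- optimInit(p)
  n <- dim(Xtr)[1]
  hist <- vector("list", cfg$epochs)
  best <- list(acc = -Inf, params = p, epoch = 0L)

  ## checkpoint selection targets the real-photograph distribution: when
  ## the validation split mixes provenances, rank checkpoints by accuracy
  ## on its real records (synthetic ones still count in the logged curve)
  valProv <- provenance(val)
  selIdx <- if (any(valProv == "real")) which(valProv == "real")
            else seq_along(yva)

  evalSplit <- function(p, X, y) {
    out <- bb$forward(p, X)
    pr <- .softmaxRows(out$logits)
    hits <- max.col(pr, ties.method = "first") == y
    loss <- -mean(log(pmax(pr[cbind(seq_along(y), y)], 1e-12)))
    c(loss = loss, acc = mean(hits), accSel = mean(hits[selIdx]))
  }

  withSeed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      lossSum <- 0; accSum <- 0; seen <- 0L
      for (b0 in seq(1L, n, by = cfg$batchSize)) {
        idx <- ord[b0:min(n, b0 + cfg$batchSize - 1L)]
        xb <- Xtr[idx, , , , drop = FALSE]
        yb <- ytr[idx]
        fw <- bb$forward(p, xb, train = TRUE)
        pr <- .softmaxRows(fw$logits)
        nb <- length(yb)
        lossSum <- lossSum -
          sum(log(pmax(pr[cbind(seq_len(nb), yb)], 1e-12)))
        accSum <- accSum +
          sum(max.col(pr, ties.method = "first") == yb)
        seen <- seen + nb
        dlog <- pr
        dlog[cbind(seq_len(nb), yb)] <-
          dlog[cbind(seq_len(nb), yb)] - 1
        dlog <- dlog / nb
        grads <- bb$backward(p, fw$cache, dlog)
        up <- adamStep(p, grads, state, cfg$learningRate)
        p <- up$params; state <- up$state
      }
      va <- evalSplit(p, Xva, yva)
      hist[[ep]] <- data.frame(epoch = ep, trainLoss = lossSum / seen,
                               trainAcc = accSum / seen,
                               valLoss = va["loss"], valAcc = va["acc"])
      if (va["accSel"] > best$acc) {
        best <- list(acc = va["accSel"], params = p, epoch = ep)
      }
    }
  })
  history <- do.call(rbind, hist)
  rownames(history) <- NULL
  structure(list(params = best$params, classes = classes,
                 history = history, cfg = cfg, bestEpoch = best$epoch,
                 backbone = bb),
            class = "stripClassifier")
}

#' @export
print.stripClassifier <- function(x, ...) {
  cat(sprintf(
    "stripClassifier (%s): classes %s; best val acc %.3f (epoch %d/%d)\n",
    x$cfg$modelName, paste(x$classes, collapse = "/"),
    max(x$history$valAcc), x$bestEpoch, x$cfg$epochs))
  invisible(x)
}

.imagesToBatch <- function(images) {
  if (is(images, "StripSet")) stackImages(images)
  else if (is.array(images) && length(dim(images)) == 4L) images
  else if (is.array(images) && length(dim(images)) == 3L)
    stackImages(list(images))
  else if (is.list(images)) stackImages(images)
  else stop("images must be a StripSet, image array, or list of images",
            call. = FALSE)
}

#' Predicted class probabilities
#'
#' Each row is a softmax distribution over the classifier's classes:
#' non-negative, summing to 1; the argmax is the predicted label.
#' @param model a `stripClassifier`.
#' @param images a [StripSet-class], one `H x W x 3` image, a list of
#'   them, or an `N x H x W x 3` batch.
#' @return `N x K` probability matrix with class column names.
#' @export
predictProba <- function(model, images) {
  stopifnot(inherits(model, "stripClassifier"))
  X <- .imagesToBatch(images)
  if (dim(X)[2] != model$cfg$inputSize || dim(X)[3] != model$cfg$inputSize)
    stop("image size does not match the classifier input size",
         call. = FALSE)
  pr <- .softmaxRows(model$backbone$forward(model$params, X)$logits)
  colnames(pr) <- model$classes
  pr
}

#' Predicted class labels (argmax of [predictProba()])
#' @inheritParams predictProba
#' @return character vector of labels.
#' @export
predictLabel <- function(model, images) {
  pr <- predictProba(model, images)
  model$classes[max.col(pr, ties.method = "first")]
}

#' Penultimate-layer features (global-average-pooled activations)
#' @inheritParams predictProba
#' @return `N x F` feature matrix, the input expected by [tsneEmbed()].
#' @export
extractFeatures <- function(model, images) {
  X <- .imagesToBatch(images)
  model$backbone$forward(model$params, X)$features
}

#' Confusion matrix of predictions against true labels
#'
#' @param preds,labels equal-length vectors of predicted and true classes
#'   (character, factor, or 0-based/1-based integers consistent with
#'   `levels`).
#' @param levels class levels fixing row/column order; inferred from the
#'   union of the inputs when omitted.
#' @return `K x K` integer matrix, rows = true class, columns = predicted
#'   class; the total equals `length(labels)`.
#' @examples
#' confusionCounts(c("a", "b", "b"), c("a", "b", "a"))
#' @export
confusionCounts <- function(preds, labels, levels = NULL) {
  if (length(preds) != length(labels))
    stop("preds and labels must have equal length", call. = FALSE)
  if (is.null(levels)) levels <- sort(unique(c(as.character(preds),
                                               as.character(labels))))
  p <- factor(as.character(preds), levels = levels)
  t <- factor(as.character(labels), levels = levels)
  cm <- table(true = t, predicted = p)
  m <- matrix(as.integer(cm), nrow = length(levels),
              dimnames = list(true = levels, predicted = levels))
  m
}

#' Per-class sensitivity, specificity, PPV, NPV and overall accuracy
#'
#' One-vs-rest reduction per class k: `TP = cm[k,k]`, `FN` the rest of row
#' k, `FP` the rest of column k, `TN` everything else; then
#' `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`, `PPV = TP/(TP+FP)`,
#' `NPV = TN/(TN+FN)`. Ratios with a zero denominator are reported as
#' `NA`, never coerced to 0. Accuracy is `trace/total`.
#'
#' @param cm confusion matrix from [confusionCounts()].
#' @return list with `perClass` (data.frame class/SEN/SPE/PPV/NPV) and
#'   `accuracy`.
#' @export
classMetrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  total <- sum(cm)
  lv <- rownames(cm)
  if (is.null(lv)) lv <- as.character(seq_len(nrow(cm)))
  rat <- function(a, b) if (b == 0) NA_real_ else a / b
  per <- do.call(rbind, lapply(seq_len(nrow(cm)), function(k) {
    TP <- cm[k, k]
    FN <- sum(cm[k, ]) - TP
    FP <- sum(cm[, k]) - TP
    TN <- total - TP - FN - FP
    data.frame(class = lv[k],
               SEN = rat(TP, TP + FN), SPE = rat(TN, TN + FP),
               PPV = rat(TP, TP + FP), NPV = rat(TN, TN + FN),
               stringsAsFactors = FALSE)
  }))
  list(perClass = per,
       accuracy = if (total == 0) NA_real_ else sum(diag(cm)) / total)
}

#' One-vs-rest ROC curves and AUC per class
#'
#' For each class the score is its predicted probability; thresholds sweep
#' the unique scores and AUC is the trapezoid area under (FPR, TPR). A
#' class absent from (or filling all of) `labels` gets `auc = NA` with
#' `undefined = TRUE`.
#'
#' @param proba `N x K` probability matrix with class column names (from
#'   [predictProba()]).
#' @param labels true labels, length `N`.
#' @return named list per class: `points` (data.frame threshold/fpr/tpr)
#'   and `auc`, plus logical `undefined`.
#' @export
rocCurves <- function(proba, labels) {
  stopifnot(is.matrix(proba), nrow(proba) == length(labels))
  classes <- colnames(proba)
  if (is.null(classes)) classes <- as.character(seq_len(ncol(proba)))
  out <- list()
  for (k in seq_along(classes)) {
    sc <- proba[, k]
    pos <- as.character(labels) == classes[k]
    nP <- sum(pos); nN <- sum(!pos)
    if (nP == 0L || nN == 0L) {
      out[[classes[k]]] <- list(points = NULL, auc = NA_real_,
                                undefined = TRUE)
      next
    }
    th <- c(Inf, sort(unique(sc), decreasing = TRUE))
    tpr <- vapply(th, function(t) sum(sc >= t & pos) / nP, numeric(1))
    fpr <- vapply(th, function(t) sum(sc >= t & !pos) / nN, numeric(1))
    auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
    out[[classes[k]]] <- list(points = data.frame(threshold = th,
                                                  fpr = fpr, tpr = tpr),
                              auc = auc, undefined = FALSE)
  }
  out
}

#' t-SNE embedding of classifier features
#'
#' Thin wrapper around the Barnes-Hut t-SNE implementation; an
#' export-only diagnostic for inspecting class separation.
#' @param features `N x F` numeric matrix (e.g. [extractFeatures()]).
#' @param perplexity t-SNE perplexity; requires `N >= 3 * perplexity`.
#' @param seed RNG seed; identical seeds give identical embeddings.
#' @return `N x 2` coordinate matrix.
#' @export
tsneEmbed <- function(features, perplexity = 30, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 3 * perplexity)
    stop(sprintf("need at least %d samples for perplexity %g",
                 ceiling(3 * perplexity), perplexity), call. = FALSE)
  withSeed(seed, {
    fit <- Rtsne::Rtsne(features, perplexity = perplexity,
                        check_duplicates = FALSE, pca = FALSE,
                        max_iter = 500)
    fit$Y
  })
}

#' Write an evaluation report bundle
#'
#' Metrics as JSON and CSV, confusion matrix, ROC points and optional
#' t-SNE coordinates as CSVs.
#' @param dir output directory (created if needed).
#' @param cm confusion matrix from [confusionCounts()].
#' @param metrics its [classMetrics()].
#' @param roc optional [rocCurves()] output.
#' @param tsne optional `N x 2` t-SNE coordinates.
#' @return invisibly, `dir`.
#' @export
writeEvalReport <- function(dir, cm, metrics, roc = NULL, tsne = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(as.data.frame(cm), file.path(dir, "confusion.csv"))
  write.csv(metrics$perClass, file.path(dir, "metrics.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(accuracy = metrics$accuracy, perClass = metrics$perClass),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(roc)) {
    pts <- do.call(rbind, lapply(names(roc), function(cl) {
      if (isTRUE(roc[[cl]]$undefined)) return(NULL)
      cbind(class = cl, roc[[cl]]$points)
    }))
    write.csv(pts, file.path(dir, "roc.csv"), row.names = FALSE)
  }
  if (!is.null(tsne))
    write.csv(data.frame(x = tsne[, 1], y = tsne[, 2]),
              file.path(dir, "tsne.csv"), row.names = FALSE)
  invisible(dir)
}
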