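## the 30-strip field-test scenario: 10 strips per class, two low
## strips called high, everything else correct
scenario30 <- function() {
  truth <- rep(c("blank", "low", "high"), each = 10)
  preds <- truth
  preds[truth == "low"][1:2] <- "high"
  list(preds = preds, truth = truth,
       cm = confusionCounts(preds, truth,
                            levels = c("blank", "low", "high")))
}

test_that("a tiny CNN learns the toy task (3-seed majority)", {
  ds <- toyStrips(100, seed = 5)
  sp <- holdoutSplit(ds, 0.8, seed = 2)
  wins <- 0L
  for (sd0 in c(3L, 7L, 11L)) {
    m <- trainClassifier(sp$train, sp$validation,
                         toyTrainConfig(epochs = 5L, seed = sd0))
    expect_equal(nrow(m$history), 5L)
    if (max(m$history$valAcc) > 0.9) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("training is seed-reproducible and validates its inputs", {
  ds <- toyStrips(10, seed = 6)
  sp <- holdoutSplit(ds, 0.8, seed = 2)
  m1 <- trainClassifier(sp$train, sp$validation,
                        toyTrainConfig(epochs = 2L, seed = 4L))
  m2 <- trainClassifier(sp$train, sp$validation,
                        toyTrainConfig(epochs = 2L, seed = 4L))
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  val2 <- sp$validation[stripLabels(sp$validation) != "blank"]
  expect_error(trainClassifier(sp$train, val2, toyTrainConfig()),
               "label sets")
  expect_error(trainConfig(modelName = "alexnet"), "unknown")
  expect_error(trainClassifier(sp$train, sp$validation,
                               trainConfig(modelName = "resnet50",
                                           inputSize = 16L)),
               "registerClassifier")
})

test_that("predicted probabilities are normalized rows with stable argmax", {
  ds <- toyStrips(10, seed = 6)
  sp <- holdoutSplit(ds, 0.8, seed = 2)
  m <- trainClassifier(sp$train, sp$validation,
                       toyTrainConfig(epochs = 2L, seed = 4L))
  pr <- predictProba(m, sp$validation)
  expect_equal(dim(pr), c(length(sp$validation), 3L))
  expect_true(all(pr >= 0))
  expect_true(all(abs(rowSums(pr) - 1) < 1e-6))
  ## duplicate inputs give identical rows
  img <- getImage(sp$validation, 1)
  two <- predictProba(m, list(img, img))
  expect_identical(two[1, ], two[2, ])
  one <- predictProba(m, img)
  expect_equal(dim(one), c(1L, 3L))
  feats <- extractFeatures(m, sp$validation)
  expect_equal(nrow(feats), length(sp$validation))
})

test_that("confusion matrices count the worked 30-strip scenario", {
  sc <- scenario30()
  expect_equal(sum(sc$cm), 30)
  expect_equal(sc$cm["low", "high"], 2L)
  offDiag <- sc$cm; diag(offDiag) <- 0L
  expect_equal(sum(offDiag), 2L)
  ## perfect predictions: diagonal with trace n
  perf <- confusionCounts(sc$truth, sc$truth)
  expect_equal(sum(diag(perf)), 30L)
  expect_equal(sum(perf) - sum(diag(perf)), 0L)
  ## empty input: all-zero matrix
  empty <- confusionCounts(character(0), character(0),
                           levels = c("a", "b"))
  expect_true(all(empty == 0L))
  expect_error(confusionCounts(1:3, 1:4), "equal length")
})

test_that("per-class metrics reproduce the worked scenario arithmetic", {
  sc <- scenario30()
  met <- classMetrics(sc$cm)
  expect_equal(met$accuracy, 28 / 30)
  pc <- met$perClass
  expect_equal(pc$SEN[pc$class == "low"], 8 / 10)
  expect_equal(pc$SPE[pc$class == "high"], 18 / 20)
  expect_equal(pc$SEN[pc$class == "blank"], 1)
  expect_equal(pc$SPE[pc$class == "blank"], 1)
  ## diagonal matrix: every ratio 1
  d <- diag(c(5L, 7L, 9L))
  rownames(d) <- colnames(d) <- c("a", "b", "c")
  md <- classMetrics(d)
  expect_true(all(md$perClass$SEN == 1) && all(md$perClass$SPE == 1))
  expect_equal(md$accuracy, 1)
  ## zero denominators surface as NA, never 0
  cm0 <- matrix(c(0L, 3L, 0L, 4L), 2, 2,    # row "a" is all zero
                dimnames = list(c("a", "b"), c("a", "b")))
  m0 <- classMetrics(cm0)
  expect_true(is.na(m0$perClass$SEN[m0$perClass$class == "a"]))
})

test_that("metrics agree exactly with a per-sample counting oracle", {
  set.seed(123)
  K <- 3L
  lv <- c("x", "y", "z")
  preds <- sample(lv, 1000, replace = TRUE)
  truth <- sample(lv, 1000, replace = TRUE)
  cm <- confusionCounts(preds, truth, levels = lv)
  met <- classMetrics(cm)
  expect_equal(met$accuracy, mean(preds == truth))
  for (cl in lv) {
    TP <- sum(preds == cl & truth == cl)
    FN <- sum(preds != cl & truth == cl)
    FP <- sum(preds == cl & truth != cl)
    TN <- sum(preds != cl & truth != cl)
    pc <- met$perClass[met$perClass$class == cl, ]
    expect_identical(pc$SEN, TP / (TP + FN))
    expect_identical(pc$SPE, TN / (TN + FP))
    expect_identical(pc$PPV, TP / (TP + FP))
    expect_identical(pc$NPV, TN / (TN + FN))
  }
})

test_that("ROC/AUC match the concordance oracle and edge cases", {
  ## perfectly separated scores
  pr <- cbind(a = c(0.9, 0.8, 0.2, 0.1), b = c(0.1, 0.2, 0.8, 0.9))
  roc <- rocCurves(pr, c("a", "a", "b", "b"))
  expect_equal(roc$a$auc, 1)
  expect_equal(roc$b$auc, 1)
  ## permuted labels: AUC ~ 0.5
  set.seed(77)
  n <- 2000
  sc <- runif(n)
  labs <- sample(c("a", "b"), n, replace = TRUE)
  pr2 <- cbind(a = sc, b = 1 - sc)
  roc2 <- rocCurves(pr2, labs)
  expect_lt(abs(roc2$a$auc - 0.5), 0.05)
  ## AUC equals the O(n^2) pairwise-concordance oracle (with ties)
  set.seed(5)
  sc3 <- round(runif(50), 1)             # ties on purpose
  lab3 <- sample(c("p", "q"), 50, replace = TRUE)
  pr3 <- cbind(p = sc3, q = 1 - sc3)
  roc3 <- rocCurves(pr3, lab3)
  expect_equal(roc3$p$auc, concordanceAUC(sc3, lab3 == "p"),
               tolerance = 1e-9)
  expect_equal(roc3$q$auc, concordanceAUC(1 - sc3, lab3 == "q"),
               tolerance = 1e-9)
  ## cross-check against an established implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- as.numeric(pROC::auc(pROC::roc(response = lab3 == "p",
                                          predictor = sc3,
                                          quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc3$p$auc, ref, tolerance = 1e-9)
  }
  ## single-class labels: flagged undefined
  roc4 <- rocCurves(pr, rep("a", 4))
  expect_true(roc4$b$undefined)
  expect_true(is.na(roc4$b$auc))
})

test_that("t-SNE embeddings are seeded diagnostics that separate blobs", {
  set.seed(9)
  f <- rbind(matrix(rnorm(45 * 4, mean = 0), ncol = 4),
             matrix(rnorm(45 * 4, mean = 6), ncol = 4))
  lab <- rep(c(1, 2), each = 45)
  expect_error(tsneEmbed(f[1:10, ], perplexity = 30), "samples")
  e1 <- tsneEmbed(f, perplexity = 10, seed = 4)
  e2 <- tsneEmbed(f, perplexity = 10, seed = 4)
  expect_equal(dim(e1), c(90L, 2L))
  expect_identical(e1, e2)
  ## silhouette of the true labels on the embedding (3-seed majority)
  silhouette <- function(emb, lab) {
    d <- as.matrix(dist(emb))
    mean(vapply(seq_along(lab), function(i) {
      a <- mean(d[i, lab == lab[i] & seq_along(lab) != i])
      b <- mean(d[i, lab != lab[i]])
      (b - a) / max(a, b)
    }, numeric(1)))
  }
  wins <- sum(vapply(1:3, function(s)
    silhouette(tsneEmbed(f, perplexity = 10, seed = s), lab) > 0.5,
    logical(1)))
  expect_gte(wins, 2L)
})
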