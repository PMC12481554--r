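synthLike <- function(ds, prefix = "syn") {
  ds@meta$provenance <- "synthetic"
  ds@meta$id <- paste0(prefix, "-", ds@meta$id)
  ds
}

test_that("1:1 mixing keeps everything when counts already balance", {
  ds <- toyStrips(10, seed = 41)        # records blocked by class
  firstHalf <- c(1:5, 11:15, 21:25)
  real <- ds[firstHalf]
  syn <- synthLike(ds[setdiff(1:30, firstHalf)])
  mixed <- mixDatasets(real, syn, ratio = 0.5)
  expect_equal(length(mixed), 30L)
  expect_equal(sum(provenance(mixed) == "real"), 15L)
  expect_equal(sum(provenance(mixed) == "synthetic"), 15L)
  expect_false(anyDuplicated(stripMeta(mixed)$id) > 0)
})

test_that("absolute-count mixing reproduces exact compositions", {
  ds <- toyStrips(20, seed = 42)
  real <- ds
  syn <- synthLike(toyStrips(20, seed = 43))
  mixed <- mixDatasets(real, syn, counts = c(6L, 54L), seed = 4)
  expect_equal(length(mixed), 60L)
  expect_equal(sum(provenance(mixed) == "real"), 6L)
  expect_equal(sum(provenance(mixed) == "synthetic"), 54L)
  ## per-class balance within each provenance pool
  m <- stripMeta(mixed)
  expect_equal(as.numeric(table(m$label[m$provenance == "real"])),
               c(2, 2, 2))
  expect_equal(as.numeric(table(m$label[m$provenance == "synthetic"])),
               c(18, 18, 18))
  ## reproducible subsampling
  mixed2 <- mixDatasets(real, syn, counts = c(6L, 54L), seed = 4)
  expect_identical(stripMeta(mixed)$id, stripMeta(mixed2)$id)
})

test_that("ratio mixing subsamples the over-represented pool per class", {
  ds <- toyStrips(20, seed = 44)
  real <- ds[c(1:10, 21:30, 41:50)]      # 10 per class
  syn <- synthLike(ds)                   # 20 per class
  mixed <- mixDatasets(real, syn, ratio = 0.5, seed = 1)
  expect_equal(sum(provenance(mixed) == "real"), 30L)
  expect_equal(sum(provenance(mixed) == "synthetic"), 30L)
  ## a class missing from one pool is an error
  noBlank <- syn[stripLabels(syn) != "blank"]
  expect_error(mixDatasets(real, noBlank, ratio = 0.5), "absent")
  expect_error(mixDatasets(real, syn, ratio = 1.2), "ratio")
})

test_that("hold-out splits are stratified seeded partitions", {
  ds <- toyStrips(100, seed = 45)        # 300 records
  sp <- holdoutSplit(ds, 0.8, seed = 7)
  expect_equal(length(sp$train), 240L)
  expect_equal(length(sp$validation), 60L)
  expect_equal(as.numeric(table(stripLabels(sp$train))), c(80, 80, 80))
  ids <- c(stripMeta(sp$train)$id, stripMeta(sp$validation)$id)
  expect_setequal(ids, stripMeta(ds)$id)
  expect_length(intersect(stripMeta(sp$train)$id,
                          stripMeta(sp$validation)$id), 0L)
  sp2 <- holdoutSplit(ds, 0.8, seed = 7)
  expect_identical(stripMeta(sp2$train)$id, stripMeta(sp$train)$id)
  expect_error(holdoutSplit(ds[1], 0.8), "fewer than 2")
  expect_error(holdoutSplit(ds, 1), "trainFrac")
})

test_that("label schemes remap deterministically from concentration", {
  ds <- toyStrips(8, seed = 46)
  m <- stripMeta(ds)
  three <- relabel(ds, "three_class")
  expect_identical(stripLabels(three), concentrationClass(m$concentration))
  expect_identical(stripLabels(three)[m$concentration == 0.75][1], "high")

  bin <- relabel(ds, "binary")
  expect_identical(unique(stripLabels(bin)[m$concentration == 0]),
                   "negative")
  expect_true(all(stripLabels(bin)[m$concentration > 0] == "positive"))

  five <- relabel(ds, "five_level")
  expect_setequal(unique(stripLabels(five)),
                  as.character(unique(m$concentration)))
  ## a balanced five-level fixture has five equal classes
  imgs <- rep(list(array(0.5, dim = c(16, 16, 3))), 50)
  meta <- data.frame(id = sprintf("f%02d", 1:50),
                     label = "blank", concentration = rep(c(0, 0.25, 0.5,
                                                            0.75, 1), 10),
                     provenance = "real")
  meta$label <- concentrationClass(meta$concentration)
  fl <- relabel(stripSet(imgs, meta), "five_level")
  expect_equal(as.numeric(table(stripLabels(fl))), rep(10, 5))

  ## synthetic records without concentration cannot be five-level
  noConc <- ds
  noConc@meta$concentration <- NA_real_
  expect_error(relabel(noConc, "five_level"), "concentration")
  ## but keep their class under binary
  expect_true(all(stripLabels(relabel(noConc, "binary")) %in%
                  c("negative", "positive")))
})
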