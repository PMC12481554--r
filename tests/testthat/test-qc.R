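test_that("SSIM is exactly 1 on identity, symmetric, and matches the
           windowed formula", {
  img <- fullStrip(conc = 0.5, contrast = 0.4, seed = 6)
  small <- img[1:32, 1:16, , drop = FALSE]
  expect_identical(ssim(small, small), 1)
  set.seed(2)
  other <- pmin(pmax(small + array(rnorm(length(small), sd = 0.05),
                                   dim = dim(small)), 0), 1)
  expect_equal(ssim(small, other), ssim(other, small), tolerance = 1e-15)
  expect_error(ssim(small, small[1:20, , , drop = FALSE]), "shape")
  expect_error(ssim(small[1:10, 1:10, , drop = FALSE],
                    small[1:10, 1:10, , drop = FALSE]), "window")

  ## independent naive double-loop oracle on a 12 x 12 patch
  set.seed(7)
  a <- array(0.5, dim = c(12, 12, 3))
  b <- pmin(pmax(a + array(rnorm(12 * 12 * 3, sd = 0.03),
                           dim = dim(a)), 0), 1)
  expect_equal(ssim(a, b), naiveSSIM(a, b), tolerance = 1e-9)
  set.seed(8)
  a2 <- array(runif(12 * 12 * 3), dim = c(12, 12, 3))
  b2 <- array(runif(12 * 12 * 3), dim = c(12, 12, 3))
  expect_equal(ssim(a2, b2), naiveSSIM(a2, b2), tolerance = 1e-9)
})

test_that("average hash and Hamming distance behave like a metric", {
  img <- randImage(24, 24, seed = 3)
  h <- avgHash(img)
  expect_length(h, 64L)
  expect_true(all(h %in% c(0L, 1L)))
  expect_equal(hammingDist(h, h), 0L)
  expect_equal(hammingDist(rep(0L, 64), rep(1L, 64)), 64L)
  expect_error(avgHash(img, bits = 60), "perfect square")
  expect_error(hammingDist(h, h[1:10]), "equal length")
  ## symmetry + triangle inequality over random triples
  set.seed(9)
  hashes <- lapply(1:30, function(i) avgHash(randImage(16, 16, seed = i)))
  for (rep in 1:100) {
    ijk <- sample(30, 3)
    d12 <- hammingDist(hashes[[ijk[1]]], hashes[[ijk[2]]])
    d21 <- hammingDist(hashes[[ijk[2]]], hashes[[ijk[1]]])
    d23 <- hammingDist(hashes[[ijk[2]]], hashes[[ijk[3]]])
    d13 <- hammingDist(hashes[[ijk[1]]], hashes[[ijk[3]]])
    expect_identical(d12, d21)
    expect_lte(d13, d12 + d23)
  }
})

test_that("greedy filtering rejects duplicates and respects thresholds", {
  ds <- toyStrips(10, seed = 61)
  ## duplicate submitted twice: second copy must fall
  dup <- repeatRecords(ds, c(1, 1, 2), c("a", "a-copy", "b"))
  res <- filterGenerated(dup, qcThresholds(ssimMax = 0.999,
                                           hammingMin = 0L))
  expect_equal(res$report$decision, c("accept", "reject", "accept"))
  expect_equal(res$report$rule[2], "ssim")

  ## vacuous thresholds accept everything
  resAll <- filterGenerated(dup, qcThresholds(ssimMax = 1.0,
                                              hammingMin = 0L))
  expect_equal(length(resAll$accepted), 3L)

  ## 10 candidates, 3 exact duplicates of earlier ones -> 7 survivors
  ten <- repeatRecords(ds, c(1:7, 1, 3, 5), sprintf("c%02d", 1:10))
  res10 <- filterGenerated(ten, qcThresholds(ssimMax = 0.999,
                                             hammingMin = 0L))
  expect_equal(length(res10$accepted), 7L)
  expect_equal(res10$report$decision[8:10], rep("reject", 3))

  ## determinism
  resA <- filterGenerated(ten, qcThresholds())
  resB <- filterGenerated(ten, qcThresholds())
  expect_identical(resA$report, resB$report)
  expect_error(filterGenerated(ds[0], qcThresholds()), "nonempty")
})

test_that("accepted sets pass an exhaustive pairwise threshold re-check", {
  ## mixed pool of simulated strips and perturbed near-duplicates
  ds <- toyStrips(25, seed = 91)
  set.seed(14)
  imgs <- lapply(seq_len(length(ds)), function(i) getImage(ds, i))
  near <- lapply(sample(length(imgs), 30, replace = TRUE), function(i)
    pmin(pmax(imgs[[i]] + array(rnorm(length(imgs[[i]]), sd = 0.005),
                                dim = dim(imgs[[i]])), 0), 1))
  pool <- c(imgs, near)
  meta <- data.frame(id = sprintf("p%03d", seq_along(pool)),
                     label = "high", concentration = 1,
                     provenance = "synthetic")
  cand <- stripSet(pool, meta)
  thr <- qcThresholds(ssimMax = 0.98, hammingMin = 2L)
  res <- filterGenerated(cand, thr)
  acc <- res$accepted
  expect_gt(length(acc), 0L)
  expect_lt(length(acc), length(cand))
  for (i in seq_len(length(acc))) for (j in seq_len(length(acc))) {
    if (i >= j) next
    a <- getImage(acc, i); b <- getImage(acc, j)
    expect_lte(ssim(a, b), thr$ssimMax)
    expect_gte(hammingDist(avgHash(a), avgHash(b)), thr$hammingMin)
  }
})
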