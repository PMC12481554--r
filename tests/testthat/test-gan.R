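test_that("configuration validation catches bad settings", {
  expect_error(ganConfig(imageSize = 20), "power of two")
  expect_error(ganConfig(imageSize = 8), "power of two")
  expect_error(ganConfig(clipValue = 0), "clipValue")
  expect_error(ganConfig(criticSteps = 0), "criticSteps")
  cfg <- toyGANConfig()
  expect_s3_class(cfg, "ganConfig")
  expect_equal(cfg$imageSize, 16L)
})

test_that("Wasserstein losses are logarithm-free linear statistics", {
  expect_equal(criticLoss(c(1, 1), c(0, 0)), -1)
  expect_equal(generatorLoss(c(0, 0)), 0)
  expect_equal(criticLoss(c(0.3, 0.7), c(0.3, 0.7)), 0)
  set.seed(4)
  r <- rnorm(10); f <- rnorm(10)
  expect_equal(criticLoss(r + 5, f + 5), criticLoss(r, f))
  expect_equal(generatorLoss(f), -mean(f))
  expect_error(criticLoss(numeric(0), 1), "nonempty")
  expect_error(generatorLoss(numeric(0)), "nonempty")
})

test_that("wasserstein1d equals brute-force optimal matching", {
  expect_equal(wasserstein1d(0, 5), 5)
  expect_equal(wasserstein1d(1:4, 1:4), 0)
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    a <- round(rnorm(n), 3)
    b <- round(rnorm(n), 3)
    expect_equal(wasserstein1d(a, b), bruteWasserstein(a, b),
                 tolerance = 1e-9)
  }
  ## unequal sizes: replicate both samples to a common size, where the
  ## sorted matching is exact, and compare to the quantile integral
  for (rep in 1:10) {
    n <- sample(2:4, 1); m <- sample(2:4, 1)
    a <- round(rnorm(n), 3); b <- round(rnorm(m), 3)
    L <- n * m
    expect_equal(wasserstein1d(a, b),
                 wasserstein1d(rep(a, each = L / n), rep(b, each = L / m)),
                 tolerance = 1e-9)
  }
  expect_error(wasserstein1d(numeric(0), 1), "nonempty")
  expect_error(wasserstein1d(c(1, NA), 1), "finite")
})

test_that("generator maps noise to deterministic bounded images", {
  for (S in c(16L, 32L)) {
    cfg <- ganConfig(noiseDim = 8, imageSize = S, baseChannels = 4,
                     seed = 3)
    gen <- buildGenerator(cfg)
    set.seed(1); z <- matrix(rnorm(2 * 8), 2)
    img1 <- stripgan:::genForward(gen$params, z, cfg)
    img2 <- stripgan:::genForward(gen$params, z, cfg)
    expect_identical(img1, img2)
    expect_equal(dim(img1), c(2L, S, S, 3L))
    expect_true(all(img1 >= 0 & img1 <= 1))
  }
})

test_that("disabling attention removes exactly the attention parameters", {
  base <- list(noiseDim = 8, imageSize = 16L, baseChannels = 4L, seed = 3)
  gOn <- buildGenerator(do.call(ganConfig, c(base, attention = TRUE)))
  gOff <- buildGenerator(do.call(ganConfig, c(base, attention = FALSE)))
  Cg <- 4L * 4L   # deepest generator scale channels
  expect_equal(paramCount(gOn) - paramCount(gOff), 3L * Cg^2 + 1L)
  cOn <- buildCritic(do.call(ganConfig, c(base, attention = TRUE)))
  cOff <- buildCritic(do.call(ganConfig, c(base, attention = FALSE)))
  Cc <- 2L * 4L
  expect_equal(paramCount(cOn) - paramCount(cOff), 3L * Cc^2 + 1L)
  expect_false(any(grepl("^att", names(gOff$params))))
})

test_that("the critic is an unbounded deterministic score", {
  cfg <- ganConfig(noiseDim = 8, imageSize = 16L, baseChannels = 4L,
                   seed = 3)
  cri <- buildCritic(cfg)
  x <- array(randImage(16, 16, seed = 5), dim = c(1, 16, 16, 3))
  s1 <- stripgan:::criticForward(cri$params, x, cfg)
  s2 <- stripgan:::criticForward(cri$params, x, cfg)
  expect_identical(s1, s2)
  expect_true(is.finite(s1))
  ## no squashing: scaling the head scales the score past [0, 1]
  cri$params$fc.W <- cri$params$fc.W * 1e4
  sBig <- stripgan:::criticForward(cri$params, x, cfg)
  cri$params$fc.W <- -cri$params$fc.W
  sNeg <- stripgan:::criticForward(cri$params, x, cfg)
  expect_true(sBig > 1 || sNeg > 1)
  expect_true(sBig < 0 || sNeg < 0)
})

test_that("training keeps critic weights clipped and losses finite", {
  ds <- toyStrips(10, seed = 31)
  sub <- ds[stripLabels(ds) == "high"]
  cfg <- toyGANConfig(steps = 12L, baseChannels = 8L, seed = 2)
  m <- trainGAN(sub, cfg, monitorEvery = 6L)
  expect_s3_class(m, "ganModel")
  h <- m$history
  expect_true(all(is.finite(h$criticLoss[h$step > 0])))
  expect_true(all(is.finite(h$genLoss[h$step > 0])))
  expect_true(all(is.finite(h$wMonitor[!is.na(h$wMonitor)])))
  for (p in m$critic$params)
    expect_true(all(abs(p) <= cfg$clipValue + 1e-12))
})

test_that("generation is seeded, labelled and sized as requested", {
  m <- toyGAN("high", seed = 5, steps = 120)
  g1 <- generateImages(m, 5, seed = 9)
  g2 <- generateImages(m, 5, seed = 9)
  expect_equal(length(g1), 5L)
  expect_identical(lapply(1:5, function(i) getImage(g1, i)),
                   lapply(1:5, function(i) getImage(g2, i)))
  expect_true(all(provenance(g1) == "synthetic"))
  expect_true(all(stripLabels(g1) == "high"))
  one <- generateImages(m, 1, seed = 2)
  expect_equal(dim(getImage(one, 1)), c(16L, 16L, 3L))
  rng <- range(unlist(lapply(1:5, function(i) range(getImage(g1, i)))))
  expect_true(rng[1] >= 0 && rng[2] <= 1)
  expect_error(generateImages(m, 0), "> 0")
})

test_that("training shrinks the band-contrast Wasserstein monitor", {
  ## distribution recovery at toy scale (stochastic; 3-seed majority)
  ds <- toyStrips(30, seed = 77)
  sub <- ds[stripLabels(ds) == "high"]
  wins <- 0L
  for (sd0 in c(5L, 6L, 7L)) {
    m <- if (sd0 == 5L) toyGAN("high", seed = 5, steps = 120)
         else trainGAN(sub, toyGANConfig(steps = 120L, seed = sd0),
                       monitorEvery = 120L)
    w <- m$history$wMonitor
    w <- w[!is.na(w)]
    if (tail(w, 1) < w[1]) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("checkpoints round-trip with a JSON sidecar", {
  m <- toyGAN("high", seed = 5, steps = 120)
  path <- file.path(withr::local_tempdir(), "gan.rds")
  saveGAN(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$imageSize, 16L)
  m2 <- loadGAN(path)
  g1 <- generateImages(m, 2, seed = 4)
  g2 <- generateImages(m2, 2, seed = 4)
  expect_identical(getImage(g1, 1), getImage(g2, 1))
})
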