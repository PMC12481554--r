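test_that("a fresh block is a bit-exact identity and maps normalize", {
  for (C in c(2L, 8L, 32L)) for (hw in c(1L, 4L, 16L)) {
    blk <- attentionBlock(C, seed = C + hw)
    expect_identical(attentionGamma(blk), 0)
    set.seed(C * 100 + hw)
    x <- array(rnorm(hw * hw * C), dim = c(hw, hw, C))
    fw <- attentionForward(blk, x)
    expect_identical(fw$y, x)
    expect_equal(sum(fw$map), 1, tolerance = 1e-6)
    expect_true(all(fw$map >= 0))
    expect_equal(dim(fw$y), dim(x))
  }
})

test_that("degenerate and invalid inputs are handled", {
  blk <- attentionBlock(2, seed = 1)
  ## uniform input: perfectly symmetric scores, uniform map
  xu <- array(1, dim = c(4, 4, 2))
  expect_equal(attentionMap(blk, xu), matrix(1 / 16, 4, 4))
  ## single spatial position: softmax weight 1, o = v(x)
  x1 <- array(c(0.3, -0.7), dim = c(1, 1, 2))
  fw <- stripgan:::.attForward(array(x1, c(1, 1, 1, 2)),
                               stripgan:::.blockParams(blk))
  expect_equal(matrix(fw$cache$o, 1), matrix(as.numeric(x1), 1) %*% blk@Wv,
               tolerance = 1e-12)
  expect_equal(as.numeric(fw$M), 1)
  ## channel mismatch and non-finite input
  expect_error(attentionForward(blk, array(0, dim = c(4, 4, 3))),
               "channels")
  expect_error(attentionForward(blk, array(NaN, dim = c(4, 4, 2))),
               "finite")
})

test_that("backward pass matches finite differences and reaches gamma", {
  set.seed(31)
  p <- list(Wf = matrix(rnorm(9), 3), Wg = matrix(rnorm(9), 3),
            Wv = matrix(rnorm(9), 3), gamma = 0.4)
  x <- array(rnorm(2 * 4 * 3 * 3), dim = c(2, 4, 3, 3))
  loss <- function(p, x) sum(sin(stripgan:::.attForward(x, p)$y))
  fw <- stripgan:::.attForward(x, p)
  bk <- stripgan:::.attBackward(cos(fw$y), p, fw$cache)
  eps <- 1e-6
  fd <- function(f1, f2) (f1 - f2) / (2 * eps)
  pp <- p; pp$gamma <- p$gamma + eps
  pm <- p; pm$gamma <- p$gamma - eps
  expect_equal(fd(loss(pp, x), loss(pm, x)), bk$dgamma, tolerance = 1e-5)
  for (nm in c("Wf", "Wg", "Wv")) for (i in c(1L, 5L, 9L)) {
    pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
    expect_equal(fd(loss(pp, x), loss(pm, x)), bk[[paste0("d", nm)]][i],
                 tolerance = 1e-5)
  }
  for (i in c(1L, 23L, 61L)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    expect_equal(fd(loss(p, xp), loss(p, xm)), bk$dx[i],
                 tolerance = 1e-5)
  }

  ## gradient flows into gamma: one optimizer step moves it off zero
  blk <- attentionBlock(3, seed = 7)
  p0 <- stripgan:::.blockParams(blk)
  set.seed(7)
  xb <- array(rnorm(1 * 4 * 4 * 3), dim = c(1, 4, 4, 3))
  f0 <- stripgan:::.attForward(xb, p0)
  b0 <- stripgan:::.attBackward(2 * f0$y, p0, f0$cache)  # d sum(y^2)
  st <- stripgan:::optimInit(p0)
  up <- stripgan:::rmspropStep(p0, list(Wf = b0$dWf, Wg = b0$dWg,
                                        Wv = b0$dWv, gamma = b0$dgamma),
                               st, 1e-3)
  expect_true(up$params$gamma != 0)
})

test_that("the forward path is purely spatial: maps commute with flips", {
  ## the direct formulation never flattens positions, so any spatial
  ## permutation of the input permutes the map identically
  blk <- attentionBlock(4, seed = 2)
  set.seed(12)
  x <- array(rnorm(6 * 6 * 4), dim = c(6, 6, 4))
  m <- attentionMap(blk, x)
  xf <- x[6:1, , , drop = FALSE]
  expect_equal(attentionMap(blk, xf), m[6:1, ], tolerance = 1e-12)
  xt <- aperm(x, c(2, 1, 3))
  expect_equal(attentionMap(blk, xt), t(m), tolerance = 1e-12)
})

test_that("after toy training the map concentrates on the band rows", {
  ## probe: attention-pooled regression of test-line contrast level; the
  ## test-band rows are the only rows informative about the target, so a
  ## trained map must upweight them (stochastic; 3-seed majority)
  trainProbe <- function(ds, tgt, seed, steps = 700, lr = 0.5) {
    blk <- attentionBlock(3, seed = seed)
    p <- stripgan:::.blockParams(blk)
    p$gamma <- 1
    w <- -1; b <- 1
    X <- stripgan:::stackImages(ds)
    n <- dim(X)[1]
    for (s in seq_len(steps)) {
      fw <- stripgan:::.attForward(X, p)
      r <- apply(fw$y - X, 1, mean)
      dz <- 2 * (w * r + b - tgt) / n
      dy <- array(0, dim = dim(X))
      for (i in seq_len(n)) dy[i, , , ] <- dz[i] * w / (length(X) / n)
      bk <- stripgan:::.attBackward(dy, p, fw$cache)
      p$Wf <- p$Wf - lr * bk$dWf
      p$Wg <- p$Wg - lr * bk$dWg
      p$Wv <- p$Wv - lr * bk$dWv
      w <- w - lr * sum(dz * r); b <- b - lr * sum(dz)
    }
    new("AttentionBlock", Wf = p$Wf, Wg = p$Wg, Wv = p$Wv,
        gamma = p$gamma)
  }
  wins <- 0L
  for (sd0 in 1:3) {
    ds <- miniStripSet(20, seed = 100 + sd0)
    tgt <- c(blank = 0, low = 0.3, high = 0.6)[stripLabels(ds)]
    blk <- trainProbe(ds, tgt, sd0)
    br <- bandRows(16)
    off <- setdiff(1:16, c(br$test, br$control))
    ratios <- vapply(which(stripLabels(ds) == "high"), function(i) {
      m <- attentionMap(blk, getImage(ds, i))
      mean(m[br$test, ]) / mean(m[off, ])
    }, numeric(1))
    if (median(ratios) > 1) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
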