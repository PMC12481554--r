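## Shared fixtures, built in code and memoized for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

## a small mixed-class 16 x 16 dataset used across modules
toyStrips <- function(nPerClass = 20, seed = 101)
  fixture(sprintf("toy-%d-%d", nPerClass, seed),
          function() miniStripSet(nPerClass, seed = seed))

## full-size render (660 x 50) of one strip with known line rows
fullStrip <- function(conc = 1, contrast = 0.6, seed = 2, noiseSd = 0.02)
  renderStrip(stripParams(conc, if (conc == 0) 0 else contrast,
                          noiseSd = noiseSd, seed = seed),
              660L, 50L)

## random valid image in [0, 1]
randImage <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), dim = c(h, w, 3))
}

## a trained toy GAN on one class, memoized (several tests inspect it)
toyGAN <- function(cls = "high", seed = 5, steps = 120) {
  fixture(sprintf("gan-%s-%d-%d", cls, seed, steps), function() {
    ds <- toyStrips(30, seed = 77)
    trainGAN(ds[stripLabels(ds) == cls],
             toyGANConfig(steps = steps, seed = seed))
  })
}

## build a StripSet repeating records of `ds` (fresh unique ids)
repeatRecords <- function(ds, idx, ids = sprintf("r%03d", seq_along(idx))) {
  m <- stripMeta(ds)[idx, , drop = FALSE]
  m$id <- ids
  stripSet(lapply(idx, function(i) getImage(ds, i)), m)
}

## brute-force W1 by minimum-cost matching over all permutations (n <= 7)
bruteWasserstein <- function(a, b) {
  stopifnot(length(a) == length(b))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_along(b)),
             function(p) mean(abs(a - b[p])), numeric(1)))
}

## naive windowed SSIM oracle: explicit loops over valid windows
naiveSSIM <- function(a, b, win = 11L, sigma = 1.5) {
  g1 <- exp(-((seq_len(win) - (win + 1) / 2)^2) / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  W <- outer(g1, g1)
  C1 <- 0.01^2; C2 <- 0.03^2
  vals <- numeric(dim(a)[3])
  for (k in seq_len(dim(a)[3])) {
    x <- a[, , k]; y <- b[, , k]
    sm <- c()
    for (i in seq_len(nrow(x) - win + 1L))
      for (j in seq_len(ncol(x) - win + 1L)) {
        xs <- x[i:(i + win - 1L), j:(j + win - 1L)]
        ys <- y[i:(i + win - 1L), j:(j + win - 1L)]
        mx <- sum(W * xs); my <- sum(W * ys)
        vx <- sum(W * xs^2) - mx^2
        vy <- sum(W * ys^2) - my^2
        cxy <- sum(W * xs * ys) - mx * my
        sm <- c(sm, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                  ((mx^2 + my^2 + C1) * (vx + vy + C2)))
      }
    vals[k] <- mean(sm)
  }
  mean(vals)
}

## O(n^2) pairwise-concordance AUC oracle (ties count 1/2)
concordanceAUC <- function(scores, pos) {
  ps <- scores[pos]; ns <- scores[!pos]
  tot <- 0
  for (p in ps) for (q in ns)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(ps) * length(ns))
}
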