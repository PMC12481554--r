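## Similarity-based quality control of generated images: SSIM + perceptual
## average-hash Hamming distance, and the greedy in-order de-duplication
## filter.

## banded matrix implementing a 1-D valid convolution with kernel g
.validConvMat <- function(n, g) {
  k <- length(g)
  key <- sprintf("vcm:%d:%d:%.6f", n, k, g[1])
  .cacheGet(key, function() {
    m <- n - k + 1L
    M <- matrix(0, nrow = m, ncol = n)
    for (i in seq_len(m)) M[i, i:(i + k - 1L)] <- g
    M
  })
}

.gaussKernel1d <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

#' Structural similarity index between two images
#'
#' Canonical SSIM: an 11 x 11 Gaussian window (sigma = 1.5) slides over
#' every valid position; local means, variances and covariance enter
#' `((2 mu_x mu_y + C1)(2 sigma_xy + C2)) /
#'  ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`
#' with `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, dynamic range `L = 1`. The
#' window map is averaged over positions and the three channels.
#' `ssim(x, x)` is exactly 1 and the measure is symmetric. Mathematically
#' SSIM lives in `[-1, 1]`; for images in `[0, 1]` it is effectively in
#' `[0, 1]` (1 means identical structure).
#'
#' @param a,b `H x W x 3` arrays in `[0, 1]` with identical shape, both at
#'   least the window size.
#' @param windowSize,sigma Gaussian window parameters (defaults 11, 1.5).
#' @return scalar SSIM value.
#' @examples
#' img <- renderStrip(stripParams(0, 0, seed = 1), 128, 16)
#' ssim(img, img)  # exactly 1
#' @export
ssim <- function(a, b, windowSize = 11L, sigma = 1.5) {
  if (!identical(dim(a), dim(b)))
    stop("images must have identical shape", call. = FALSE)
  d <- dim(a)
  if (d[1] < windowSize || d[2] < windowSize)
    stop("images smaller than the SSIM window", call. = FALSE)
  g <- .gaussKernel1d(windowSize, sigma)
  Gr <- .validConvMat(d[1], g)
  Gc <- t(.validConvMat(d[2], g))
  C1 <- 0.01^2; C2 <- 0.03^2
  vals <- numeric(d[3])
  for (k in seq_len(d[3])) {
    x <- a[, , k]; y <- b[, , k]
    mux <- Gr %*% x %*% Gc
    muy <- Gr %*% y %*% Gc
    sxx <- Gr %*% (x * x) %*% Gc - mux * mux
    syy <- Gr %*% (y * y) %*% Gc - muy * muy
    sxy <- Gr %*% (x * y) %*% Gc - mux * muy
    smap <- ((2 * mux * muy + C1) * (2 * sxy + C2)) /
      ((mux * mux + muy * muy + C1) * (sxx + syy + C2))
    vals[k] <- mean(smap)
  }
  mean(vals)
}

#' Perceptual average hash of an image
#'
#' Grayscale, bilinear resize to `sqrt(bits) x sqrt(bits)`, threshold each
#' cell at the mean: near-duplicate images share most bits.
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param bits hash length; must be a perfect square (default 64).
#' @return integer 0/1 vector of length `bits`.
#' @export
avgHash <- function(img, bits = 64L) {
  s <- sqrt(bits)
  if (abs(s - round(s)) > 1e-12)
    stop("bits must be a perfect square", call. = FALSE)
  s <- as.integer(round(s))
  g <- toGray(img)
  small <- resizeBilinear(array(g, dim = c(dim(g), 1L)), s, s)[, , 1]
  as.integer(small > mean(small))
}

#' Hamming distance between two bit vectors
#' @param h1,h2 equal-length 0/1 integer vectors (e.g. from [avgHash()]).
#' @return integer count of differing bits, in `[0, length(h1)]`.
#' @examples
#' hammingDist(c(0L, 1L, 1L), c(1L, 1L, 0L))  # 2
#' @export
hammingDist <- function(h1, h2) {
  if (length(h1) != length(h2))
    stop("hashes must have equal length", call. = FALSE)
  sum(h1 != h2)
}

#' QC thresholds for generated-image filtering
#'
#' The source text states that SSIM and Hamming distance were used to
#' remove overly similar generated images but not the cutoffs; the
#' defaults here are a conservative de-duplication choice and are fully
#' configurable.
#' @param ssimMax reject a candidate whose SSIM against any accepted image
#'   exceeds this (default 0.95).
#' @param hammingMin reject a candidate whose hash Hamming distance to any
#'   accepted image falls below this (default 4).
#' @param hashBits average-hash length, a perfect square (default 64).
#' @return validated list of class `qcThresholds`.
#' @export
qcThresholds <- function(ssimMax = 0.95, hammingMin = 4L, hashBits = 64L) {
  .assertScalar(ssimMax, "ssimMax"); .assertScalar(hammingMin, "hammingMin")
  if (ssimMax <= 0 || ssimMax > 1)
    stop("ssimMax must be in (0, 1]", call. = FALSE)
  if (hammingMin < 0) stop("hammingMin must be >= 0", call. = FALSE)
  s <- sqrt(hashBits)
  if (abs(s - round(s)) > 1e-12)
    stop("hashBits must be a perfect square", call. = FALSE)
  structure(list(ssimMax = ssimMax, hammingMin = as.integer(hammingMin),
                 hashBits = as.integer(hashBits)),
            class = "qcThresholds")
}

#' Filter generated images by pairwise similarity
#'
#' Greedy pass in input order: a candidate is rejected iff, against any
#' already-accepted image, `ssim > ssimMax` OR `hamming < hammingMin`.
#' Deterministic. By default both metrics are always consulted so the
#' accepted set provably contains no pair violating either threshold;
#' `prefilter = TRUE` skips the SSIM computation when the Hamming distance
#' is at least `2 * hammingMin` (an O(n k) speedup for large batches, at
#' the cost of that guarantee holding only for hash-similar pairs).
#'
#' @param candidates a nonempty [StripSet-class] of generated images.
#' @param thresholds a [qcThresholds()].
#' @param prefilter use the hash prefilter before computing SSIM
#'   (default `FALSE`).
#' @return list with `accepted` (a [StripSet-class]) and `report` (a
#'   data.frame: id, decision, rule, bestSsim, minHamming).
#' @export
filterGenerated <- function(candidates, thresholds = qcThresholds(),
                            prefilter = FALSE) {
  stopifnot(is(candidates, "StripSet"),
            inherits(thresholds, "qcThresholds"))
  n <- length(candidates)
  if (!n) stop("candidates must be nonempty", call. = FALSE)
  hashes <- lapply(seq_len(n), function(i)
    avgHash(getImage(candidates, i), thresholds$hashBits))
  keep <- logical(n)
  accIdx <- integer(0)
  rule <- character(n); bestS <- rep(NA_real_, n)
  minH <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    img <- NULL
    rejected <- FALSE; why <- ""
    bs <- NA_real_; mh <- NA_integer_
    for (j in accIdx) {
      hd <- hammingDist(hashes[[i]], hashes[[j]])
      mh <- if (is.na(mh)) hd else min(mh, hd)
      if (hd < thresholds$hammingMin) {
        rejected <- TRUE; why <- "hamming"; break
      }
      if (!prefilter || hd < 2L * thresholds$hammingMin) {
        if (is.null(img)) img <- getImage(candidates, i)
        sv <- ssim(img, getImage(candidates, j))
        bs <- if (is.na(bs)) sv else max(bs, sv)
        if (sv > thresholds$ssimMax) {
          rejected <- TRUE; why <- "ssim"; break
        }
      }
    }
    keep[i] <- !rejected
    rule[i] <- if (rejected) why else "accepted"
    bestS[i] <- bs; minH[i] <- mh
    if (!rejected) accIdx <- c(accIdx, i)
  }
  report <- data.frame(id = stripMeta(candidates)$id,
                       decision = ifelse(keep, "accept", "reject"),
                       rule = rule, bestSsim = bestS, minHamming = minH,
                       stringsAsFactors = FALSE)
  list(accepted = candidates[keep], report = report)
}
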