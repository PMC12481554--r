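## Internal helpers shared across modules: seeded evaluation, argument
## checking, and the bilinear image primitives (resize, rotation warps).

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so library code never
#' perturbs the session RNG stream.
#' @noRd
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## derive a reproducible child seed (kept below 2^31; multipliers sized so
## every intermediate product stays exactly representable in a double)
childSeed <- function(seed, offset) {
  s <- as.double(seed) %% 2147483647
  o <- as.double(offset) %% 2147483647
  (s * 69069 + o * 7919 + 12345) %% 2147483647
}

.assertScalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

.assertImage <- function(img, name = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("'%s' must be an H x W x 3 array", name), call. = FALSE)
  if (anyNA(img) || !all(is.finite(img)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  if (min(img) < 0 || max(img) > 1)
    stop(sprintf("'%s' must have values in [0, 1]", name), call. = FALSE)
  if (any(dim(img)[1:2] < 8L))
    stop(sprintf("'%s' must be at least 8 x 8 pixels", name), call. = FALSE)
  invisible(img)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Bilinear resize of an H x W x C array
#'
#' Output pixel centres are mapped into the input grid with the half-pixel
#' convention, so resizing to the same dimensions is the identity.
#' @noRd
resizeBilinear <- function(img, hOut, wOut) {
  d <- dim(img)
  h <- d[1]; w <- d[2]; nc <- d[3]
  if (h == hOut && w == wOut) return(img)
  sy <- h / hOut; sx <- w / wOut
  ys <- pmin(pmax((seq_len(hOut) - 0.5) * sy + 0.5, 1), h)
  xs <- pmin(pmax((seq_len(wOut) - 0.5) * sx + 0.5, 1), w)
  y0 <- pmin(floor(ys), h - 1L); y1 <- y0 + 1
  x0 <- pmin(floor(xs), w - 1L); x1 <- x0 + 1
  wy <- ys - y0; wx <- xs - x0
  out <- array(0, dim = c(hOut, wOut, nc))
  for (k in seq_len(nc)) {
    ch <- img[, , k]
    a <- ch[y0, x0, drop = FALSE]; b <- ch[y0, x1, drop = FALSE]
    cc <- ch[y1, x0, drop = FALSE]; dd <- ch[y1, x1, drop = FALSE]
    top <- a * (1 - wx)[col(a)] + b * wx[col(b)]
    bot <- cc * (1 - wx)[col(cc)] + dd * wx[col(dd)]
    out[, , k] <- top * (1 - wy)[row(top)] + bot * wy[row(bot)]
  }
  out
}

#' Sparse warp matrix for a rotation about the image centre
#'
#' Row r of the matrix holds the (at most four) bilinear weights that the
#' r-th output pixel takes from the input pixels; pixels sampled outside the
#' frame get zero weight (zero fill). Cosine/sine values within 1e-12 of
#' 0 or +-1 are snapped so that multiples of 90 degrees are exact pixel
#' permutations and angle 0 is the bit-exact identity.
#' @noRd
warpMatrix <- function(h, w, angleDeg) {
  key <- sprintf("warp:%d:%d:%.9f", h, w, angleDeg %% 360)
  .cacheGet(key, function() {
    th <- (angleDeg %% 360) * pi / 180
    cs <- cos(th); sn <- sin(th)
    snap <- function(v) {
      for (t in c(-1, 0, 1)) if (abs(v - t) < 1e-12) return(t)
      v
    }
    cs <- snap(cs); sn <- snap(sn)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    ## inverse map: source = R(-theta) (dest - centre) + centre
    ro <- rep(seq_len(h), times = w); co <- rep(seq_len(w), each = h)
    dy <- ro - cy; dx <- co - cx
    sy <- cs * dy - sn * dx + cy
    sx <- sn * dy + cs * dx + cx
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    n <- h * w
    ii <- integer(0); jj <- integer(0); vv <- numeric(0)
    for (oy in 0:1) for (ox in 0:1) {
      yy <- y0 + oy; xx <- x0 + ox
      wgt <- (if (oy == 0) 1 - fy else fy) * (if (ox == 0) 1 - fx else fx)
      ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w & wgt > 0
      ii <- c(ii, which(ok))
      jj <- c(jj, yy[ok] + (xx[ok] - 1) * h)
      vv <- c(vv, wgt[ok])
    }
    Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  })
}

#' Rotate an image about its centre with bilinear interpolation, zero fill
#' @noRd
rotateImage <- function(img, angleDeg) {
  d <- dim(img)
  if ((angleDeg %% 360) == 0) return(img)
  M <- warpMatrix(d[1], d[2], angleDeg)
  out <- as.matrix(M %*% matrix(img, nrow = d[1] * d[2]))
  array(out, dim = d)
}

#' Horizontal/vertical mirror of an image
#' @param img an `H x W x 3` image array in `[0, 1]`.
#' @param axis `"horizontal"` flips left-right (columns), `"vertical"` flips
#'   top-bottom (rows).
#' @return the flipped image array, same dimensions.
#' @examples
#' img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
#' identical(flipImage(flipImage(img, "vertical"), "vertical"), img)
#' @export
flipImage <- function(img, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  d <- dim(img)
  if (axis == "horizontal") img[, d[2]:1, , drop = FALSE]
  else img[d[1]:1, , , drop = FALSE]
}

## luminance = plain channel mean (strips are near-greyscale)
toGray <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / 3
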