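## Image standardization chain: edge crop to 660 x 50, zero-pad to
## 660 x 660, line-based crop to 128 x 128, and the 3.6-degree rotation
## augmentation. Coordinates are row-major with the origin at the top-left.

#' Crop a photograph to the strip's bounding box and standardize size
#'
#' Foreground is taken as the pixels whose luminance exceeds `threshold`;
#' the tight bounding box of that region is cropped and bilinearly resized
#' to `height x width` (default `660 x 50`, the standardized raw
#' resolution). Simulator output that is already strip-only passes through
#' unchanged when it has the target size.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param height,width target size (default 660 x 50).
#' @param threshold luminance threshold separating strip from background.
#' @return `height x width x 3` array.
#' @export
cropToEdges <- function(img, height = 660L, width = 50L,
                        threshold = 0.05) {
  .assertImage(img)
  g <- toGray(img)
  fg <- g > threshold
  if (!any(fg))
    stop(structure(class = c("segmentationFailure", "error", "condition"),
                   list(message = "no foreground region found above threshold",
                        call = sys.call())))
  rr <- range(which(rowSums(fg) > 0))
  cr <- range(which(colSums(fg) > 0))
  crop <- img[rr[1]:rr[2], cr[1]:cr[2], , drop = FALSE]
  resizeBilinear(crop, height, width)
}

#' Zero-pad a tall strip image into a square
#'
#' Pads columns symmetrically with exact zeros so a `660 x 50` image
#' becomes `660 x 660` with the original 50 columns centred
#' (305 columns of padding on each side).
#' @param img `H x W x 3` array with `W < H` and `H - W` even.
#' @return `H x H x 3` array.
#' @export
padToSquare <- function(img) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L)
    stop("input must be an H x W x 3 array", call. = FALSE)
  h <- d[1]; w <- d[2]
  if (w >= h) stop("image is already as wide as it is tall", call. = FALSE)
  if ((h - w) %% 2L != 0L)
    stop("height minus width must be even for symmetric padding",
         call. = FALSE)
  pad <- (h - w) %/% 2L
  out <- array(0, dim = c(h, h, 3L))
  out[, (pad + 1L):(pad + w), ] <- img
  out
}

#' Locate the control and test line rows on a padded strip image
#'
#' Computes the mean luminance of each row over the non-zero (strip)
#' columns, smooths it with a moving average, and returns the two deepest
#' local minima — the two dark bands. Fails with a `lineDetectionFailure`
#' condition (carrying the profile) when fewer than two minima exist, e.g.
#' on a blank strip where only the control line developed.
#' @param img `H x W x 3` array.
#' @param smooth moving-average window in rows; the default is the
#'   nominal band thickness (4% of the height, forced odd), which turns
#'   each flat dark band of the profile into a valley peaked at the band
#'   centre.
#' @return sorted integer vector of the two line rows.
#' @export
detectLineRows <- function(img, smooth = NULL) {
  g <- toGray(img)
  cols <- which(colSums(g) > 0)
  if (!length(cols)) cols <- seq_len(ncol(g))
  prof <- rowMeans(g[, cols, drop = FALSE])
  if (is.null(smooth)) smooth <- max(5L, round(0.04 * length(prof)))
  if (smooth %% 2L == 0L) smooth <- smooth + 1L
  k <- rep(1 / smooth, smooth)
  sm <- stats::filter(prof, k, sides = 2)
  sm[is.na(sm)] <- prof[is.na(sm)]
  sm <- as.numeric(sm)
  n <- length(sm)
  ## strict local minima against a +-bandwidth neighbourhood
  half <- max(2L, round(0.02 * n))
  isMin <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    sm[i] == min(sm[lo:hi]) && sm[i] < mean(sm) - 1e-6
  }, logical(1))
  cand <- which(isMin)
  ## merge plateaus / adjacent minima into one candidate each
  if (length(cand)) {
    grp <- cumsum(c(1, diff(cand) > half))
    cand <- vapply(split(cand, grp), function(ix) ix[which.min(sm[ix])],
                   numeric(1))
  }
  if (length(cand) < 2L) {
    cond <- structure(
      class = c("lineDetectionFailure", "error", "condition"),
      list(message = sprintf(
        "found %d intensity minima, need 2 (blank strip?)", length(cand)),
        call = sys.call(), profile = prof))
    stop(cond)
  }
  sort(cand[order(sm[cand])][1:2])
}

#' Crop a padded strip image around its two lines and resize to 128 x 128
#'
#' The crop window spans the two line rows extended by a symmetric margin
#' of `margin` times the inter-line distance on each side (full image
#' width), then is bilinearly resized to `size x size`.
#'
#' @param img square `H x H x 3` array (output of [padToSquare()]).
#' @param lineRows integer vector `c(r1, r2)` of the two line rows, or
#'   `NULL` for automatic detection via [detectLineRows()].
#' @param size output side length (default 128).
#' @param margin margin as a fraction of the inter-line distance
#'   (default 0.2).
#' @return `size x size x 3` array.
#' @export
cropLines <- function(img, lineRows = NULL, size = 128L, margin = 0.2) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L)
    stop("input must be an H x W x 3 array", call. = FALSE)
  if (is.null(lineRows)) lineRows <- detectLineRows(img)
  lineRows <- sort(as.integer(lineRows))
  if (length(lineRows) != 2L || lineRows[1] < 1L || lineRows[2] > d[1])
    stop("lineRows must be two rows inside the image", call. = FALSE)
  m <- max(1L, round(margin * (lineRows[2] - lineRows[1])))
  r1 <- max(1L, lineRows[1] - m)
  r2 <- min(d[1], lineRows[2] + m)
  resizeBilinear(img[r1:r2, , , drop = FALSE], size, size)
}

#' Rotation augmentation: a full revolution in fixed angular steps
#'
#' Returns `round(360 / stepDeg)` copies of the input rotated about its
#' centre by `k * stepDeg`, `k = 0 ... N-1`, with bilinear interpolation
#' and zero fill outside the frame. The default step of 3.6 degrees yields
#' 100 images per input. The step must divide 360 (within 1e-9) — partial
#' revolutions are rejected.
#'
#' @param img `H x W x 3` array.
#' @param stepDeg angular step in degrees, `0 < stepDeg <= 360`.
#' @return list of rotated image arrays; element 1 is the input itself.
#' @examples
#' img <- renderStrip(stripParams(0, 0, seed = 1), 128, 16)
#' length(augmentRotations(img, 90))
#' @export
augmentRotations <- function(img, stepDeg = 3.6) {
  .assertScalar(stepDeg, "stepDeg")
  if (stepDeg <= 0 || stepDeg > 360)
    stop("stepDeg must be in (0, 360]", call. = FALSE)
  n <- 360 / stepDeg
  if (abs(n - round(n)) > 1e-9)
    stop("stepDeg must divide 360 exactly (no partial revolutions)",
         call. = FALSE)
  n <- as.integer(round(n))
  lapply(seq_len(n) - 1L, function(k) rotateImage(img, k * stepDeg))
}

#' Batched rotation sweep over a StripSet
#'
#' Applies the full [augmentRotations()] schedule to every image, with one
#' sparse warp per angle shared across the whole batch. With
#' `collect = FALSE` only the number of derived images is counted — that
#' mode streams the full augmentation (e.g. 3000 inputs at a 3.6-degree
#' step is 300,000 derived images) without materializing it.
#'
#' @param x a [StripSet-class] with in-memory images of identical size.
#' @param stepDeg angular step (default 3.6 degrees, i.e. 100 rotations).
#' @param collect if `TRUE` return the augmented [StripSet-class] with an
#'   `angle` metadata column; if `FALSE` return the integer count of
#'   derived images.
#' @return a `StripSet` or an integer count.
#' @export
rotationSweep <- function(x, stepDeg = 3.6, collect = TRUE) {
  stopifnot(is(x, "StripSet"))
  nAng <- 360 / stepDeg
  if (abs(nAng - round(nAng)) > 1e-9)
    stop("stepDeg must divide 360 exactly", call. = FALSE)
  nAng <- as.integer(round(nAng))
  nImg <- length(x)
  if (!nImg) return(if (collect) x else 0L)
  d <- dim(getImage(x, 1))
  X <- matrix(0, nrow = d[1] * d[2], ncol = 3L * nImg)
  for (i in seq_len(nImg)) {
    im <- getImage(x, i)
    if (!identical(dim(im), d)) stop("images must share one size")
    X[, (3L * i - 2L):(3L * i)] <- matrix(im, ncol = 3L)
  }
  total <- 0L
  outImgs <- if (collect) vector("list", nImg * nAng) else NULL
  outMeta <- if (collect) vector("list", nAng) else NULL
  for (k in seq_len(nAng) - 1L) {
    ang <- k * stepDeg
    R <- if (ang == 0) X else as.matrix(warpMatrix(d[1], d[2], ang) %*% X)
    total <- total + nImg
    if (collect) {
      for (i in seq_len(nImg))
        outImgs[[k * nImg + i]] <-
          array(R[, (3L * i - 2L):(3L * i)], dim = d)
      m <- x@meta
      m$id <- sprintf("%s-rot%05.1f", m$id, ang)
      m$angle <- ang
      outMeta[[k + 1L]] <- m
    }
  }
  if (!collect) return(total)
  stripSet(outImgs, do.call(rbind, outMeta), x@labelScheme)
}

#' Run the full standardization chain on one image
#'
#' [cropToEdges()] then [padToSquare()] then [cropLines()]; rotation
#' augmentation is applied afterwards on the final `128 x 128` image (the
#' chain rotates the cropped image, not the raw photograph — recorded in
#' the pipeline configuration).
#' @param img raw `H x W x 3` photograph or simulator output.
#' @param lineRows optional explicit line rows (post-padding coordinates).
#' @param size final side length (default 128).
#' @return `size x size x 3` array.
#' @export
standardizeStrip <- function(img, lineRows = NULL, size = 128L) {
  cropLines(padToSquare(cropToEdges(img)), lineRows = lineRows,
            size = size)
}
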