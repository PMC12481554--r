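## Procedural LFIA strip-image simulator.
##
## The renderer emulates the statistical structure of strip photographs:
## a bright membrane, a control band that always develops, a test band whose
## darkness grows with analyte concentration, a multiplicative lighting
## gradient of configurable direction (a nuisance variable, as in captured
## photos taken under light sources from different directions), and additive
## Gaussian sensor noise clipped to [0, 1].

## fixed band geometry (fractions of image height)
.CONTROL_FRAC <- 0.30
.TEST_FRAC <- 0.60
.BAND_FRAC <- 0.04
.MEMBRANE <- 0.85

#' Row indices of the control and test bands for a given image height
#'
#' The simulator places the control line at 30% and the test line at 60% of
#' the image height, each 4% of the height thick. Downstream line-detection
#' code uses these as ground truth for simulated images.
#' @param height image height in pixels.
#' @return list with integer vectors `control` and `test` of band row
#'   indices and scalars `controlRow`/`testRow` (band centres).
#' @examples
#' bandRows(128)$testRow
#' @export
bandRows <- function(height) {
  half <- max(1, round(.BAND_FRAC * height / 2))
  ctr <- round(.CONTROL_FRAC * height)
  tst <- round(.TEST_FRAC * height)
  list(control = max(1, ctr - half):min(height, ctr + half - 1),
       test = max(1, tst - half):min(height, tst + half - 1),
       controlRow = ctr, testRow = tst)
}

#' Render one simulated LFIA strip image
#'
#' Deterministic given identical parameters (the seed inside `params` drives
#' the noise). The image is built as: uniform membrane intensity 0.85;
#' multiplicative darkening of the control/test band rows by their
#' contrasts; a multiplicative linear lighting ramp oriented at
#' `lightingAngle` with relative amplitude `lightingAmp`; additive Gaussian
#' noise of sd `noiseSd`; final clip to `[0, 1]`.
#'
#' @param params a [StripParams-class] object.
#' @param height,width output size in pixels (`height >= 64`,
#'   `width >= 16`). Default `660 x 50`, the standardized raw resolution;
#'   tests use `128 x 16` minis.
#' @param lightingAmp relative amplitude of the lighting ramp (default
#'   0.15, i.e. +-15% across the frame).
#' @return an `height x width x 3` array in `[0, 1]` with attribute
#'   `origin = "synthetic"` and attribute `bandRows` recording the true band
#'   rows.
#' @examples
#' img <- renderStrip(stripParams(0.5, 0.4, seed = 7), 128, 16)
#' dim(img)
#' @export
renderStrip <- function(params, height = 660L, width = 50L,
                        lightingAmp = 0.15) {
  stopifnot(is(params, "StripParams"))
  validObject(params)
  .assertScalar(height, "height"); .assertScalar(width, "width")
  .assertScalar(lightingAmp, "lightingAmp")
  if (height < 64 || width < 16)
    stop("render size must be at least 64 x 16", call. = FALSE)
  height <- as.integer(height); width <- as.integer(width)

  base <- matrix(.MEMBRANE, nrow = height, ncol = width)
  br <- bandRows(height)
  base[br$control, ] <- base[br$control, ] * (1 - params@controlContrast)
  base[br$test, ] <- base[br$test, ] * (1 - params@testContrast)

  if (lightingAmp != 0) {
    th <- params@lightingAngle * pi / 180
    ry <- (seq_len(height) - (height + 1) / 2)
    rx <- (seq_len(width) - (width + 1) / 2)
    proj <- outer(ry, rx, function(y, x) cos(th) * x + sin(th) * y)
    ext <- max(abs(proj))
    if (ext > 0) base <- base * (1 + lightingAmp * proj / ext)
  }

  img <- array(rep(base, 3L), dim = c(height, width, 3L))
  ## slight warm tint so channels are not identical
  img[, , 3] <- img[, , 3] * 0.97
  if (params@noiseSd > 0) {
    img <- withSeed(params@seed,
                    img + array(rnorm(length(img), sd = params@noiseSd),
                                dim = dim(img)))
  }
  img <- clip01(img)
  attr(img, "origin") <- "synthetic"
  attr(img, "bandRows") <- c(control = br$controlRow, test = br$testRow)
  img
}

#' Test-band darkness statistic of a strip image
#'
#' Mean intensity over non-band rows minus mean intensity over the
#' test-band rows: 0 for a blank strip, increasing with test-line contrast.
#' Used as the monotone-signal oracle and as the GAN training monitor
#' marginal.
#' @param img `H x W x 3` image array.
#' @return scalar darkness value.
#' @export
testBandDarkness <- function(img) {
  h <- dim(img)[1]
  br <- bandRows(h)
  g <- toGray(img)
  off <- setdiff(seq_len(h), c(br$control, br$test))
  mean(g[off, ]) - mean(g[br$test, ])
}

## draw per-strip latent parameters for one concentration level
.sampleParams <- function(concentration, noiseSd, seed) {
  cls <- concentrationClass(concentration)
  tc <- if (concentration == 0) 0 else
    min(1, max(0.02, 0.15 + 0.5 * concentration + rnorm(1, sd = 0.03)))
  cc <- min(1, max(0.05, rnorm(1, mean = 0.6, sd = 0.05)))
  stripParams(concentration, testContrast = tc, controlContrast = cc,
              lightingAngle = runif(1, 0, 360), noiseSd = noiseSd,
              seed = seed)
}

#' Simulate a class-balanced labelled strip dataset
#'
#' Draws `nPerClass` strips for each of the three classes. Within the low
#' and high classes the concentration is drawn uniformly from the two
#' member levels (0.25/0.5 and 0.75/1 ug/mL); lighting angles are uniform
#' on `[0, 360)`; test-line contrast is drawn around a mean that increases
#' linearly with concentration. Fully reproducible from `seed`.
#'
#' @param nPerClass number of strips per class (>= 1).
#' @param seed integer RNG seed.
#' @param profile list of rendering options: `height`, `width` (default
#'   660 x 50), `noiseSd` (default 0.02), `lightingAmp` (default 0.15).
#' @return a [StripSet-class] with `3 * nPerClass` records, provenance
#'   `"real"` (the simulator stands in for captured photographs), metadata
#'   columns `concentration`, `seed`, `testRow`, `controlRow`.
#' @examples
#' ds <- sampleStripSet(2, seed = 1,
#'                      profile = list(height = 128, width = 16))
#' table(stripLabels(ds))
#' @export
sampleStripSet <- function(nPerClass, seed = 1L, profile = list()) {
  .assertScalar(nPerClass, "nPerClass")
  if (nPerClass < 1) stop("nPerClass must be >= 1", call. = FALSE)
  prof <- modifyList(list(height = 660L, width = 50L, noiseSd = 0.02,
                          lightingAmp = 0.15), profile)
  concPools <- list(blank = 0, low = c(0.25, 0.5), high = c(0.75, 1.0))
  withSeed(seed, {
    images <- vector("list", 3L * nPerClass)
    rows <- vector("list", 3L * nPerClass)
    k <- 0L
    for (cls in .CLASS_LEVELS) {
      pool <- concPools[[cls]]
      for (j in seq_len(nPerClass)) {
        k <- k + 1L
        conc <- if (length(pool) == 1L) pool else sample(pool, 1L)
        pseed <- floor(runif(1, 0, 2^31 - 1))
        p <- .sampleParams(conc, prof$noiseSd, pseed)
        img <- renderStrip(p, prof$height, prof$width, prof$lightingAmp)
        br <- attr(img, "bandRows")
        images[[k]] <- img
        rows[[k]] <- data.frame(
          id = sprintf("sim-%d-%s-%04d", as.integer(seed), cls, j),
          label = cls, concentration = conc, provenance = "real",
          seed = pseed, testRow = br[["test"]],
          controlRow = br[["control"]], stringsAsFactors = FALSE)
      }
    }
    stripSet(images, do.call(rbind, rows))
  })
}

#' Read a PNG strip image as an H x W x 3 array in [0, 1]
#' @param path PNG file path.
#' @return image array.
#' @export
readStripPNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' Write a StripSet to a directory of PNGs plus a CSV manifest
#'
#' Images land in `<root>/<label>/<id>.png`; the manifest
#' `<root>/manifest.csv` has columns `path`, `class`, `concentration`,
#' `seed`, `provenance` (plus any extra metadata columns).
#' @param x a [StripSet-class] with in-memory images.
#' @param root output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
writeStripSet <- function(x, root) {
  stopifnot(is(x, "StripSet"))
  m <- x@meta
  paths <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    dir <- file.path(root, m$label[i])
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths[i] <- file.path(dir, paste0(m$id[i], ".png"))
    png::writePNG(getImage(x, i), paths[i])
  }
  man <- data.frame(path = paths, class = m$label,
                    concentration = m$concentration,
                    seed = if ("seed" %in% names(m)) m$seed else NA,
                    provenance = m$provenance, stringsAsFactors = FALSE)
  write.csv(man, file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Load a StripSet from a manifest written by [writeStripSet()]
#' @param root dataset directory containing `manifest.csv`.
#' @param lazy if `TRUE` (default) keep file paths and load pixels on
#'   demand via [getImage()].
#' @return a [StripSet-class].
#' @export
readStripSet <- function(root, lazy = TRUE) {
  man <- read.csv(file.path(root, "manifest.csv"),
                  stringsAsFactors = FALSE)
  meta <- data.frame(id = sub("\\.png$", "", basename(man$path)),
                     label = man$class, concentration = man$concentration,
                     provenance = man$provenance, seed = man$seed,
                     stringsAsFactors = FALSE)
  images <- if (lazy) as.list(man$path) else lapply(man$path, readStripPNG)
  stripSet(images, meta)
}
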