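## S4 classes for the central data objects.

.CLASS_LEVELS <- c("blank", "low", "high")
.CONC_LEVELS <- c(0, 0.25, 0.5, 0.75, 1.0)

#' Map analyte concentration to the three-class label
#'
#' Concentration 0 is `blank`; 0.25 and 0.5 ug/mL are `low`; 0.75 and
#' 1 ug/mL are `high`.
#' @param concentration numeric vector of concentrations in ug/mL; each must
#'   be one of 0, 0.25, 0.5, 0.75, 1.
#' @return character vector of labels in `c("blank", "low", "high")`.
#' @examples
#' concentrationClass(c(0, 0.5, 0.75))
#' @export
concentrationClass <- function(concentration) {
  if (!all(concentration %in% .CONC_LEVELS))
    stop("concentration must be one of 0, 0.25, 0.5, 0.75, 1 ug/mL",
         call. = FALSE)
  ifelse(concentration == 0, "blank",
         ifelse(concentration <= 0.5, "low", "high"))
}

#' StripParams: latent description of one simulated LFIA strip
#'
#' Captures everything [renderStrip()] needs: the class label and its
#' consistent analyte concentration, the unitless optical contrasts of the
#' test and control lines, the direction of the (multiplicative) lighting
#' gradient, the sensor noise level, and the RNG seed that makes the render
#' reproducible.
#'
#' Validity enforces the domain invariants: the label must agree with the
#' concentration grouping, the test line has zero contrast at zero
#' concentration, and the control line always develops
#' (`controlContrast > 0`).
#'
#' @slot classLabel one of `"blank"`, `"low"`, `"high"`.
#' @slot concentration analyte concentration in ug/mL, one of
#'   0, 0.25, 0.5, 0.75, 1.
#' @slot testContrast unitless test-line contrast in `[0, 1]`.
#' @slot controlContrast unitless control-line contrast in `(0, 1]`.
#' @slot lightingAngle lighting-gradient direction in degrees `[0, 360)`.
#' @slot noiseSd additive Gaussian noise standard deviation (>= 0).
#' @slot seed integer RNG seed.
#' @export
setClass("StripParams",
  representation(classLabel = "character", concentration = "numeric",
                 testContrast = "numeric", controlContrast = "numeric",
                 lightingAngle = "numeric", noiseSd = "numeric",
                 seed = "numeric"),
  validity = function(object) {
    msg <- character(0)
    num1 <- function(x) length(x) == 1L && is.finite(x)
    if (!(length(object@classLabel) == 1L &&
          object@classLabel %in% .CLASS_LEVELS))
      msg <- c(msg, "classLabel must be one of blank/low/high")
    if (!num1(object@concentration) ||
        !(object@concentration %in% .CONC_LEVELS))
      msg <- c(msg, "concentration must be in {0, 0.25, 0.5, 0.75, 1}")
    else if (length(object@classLabel) == 1L &&
             object@classLabel %in% .CLASS_LEVELS &&
             concentrationClass(object@concentration) != object@classLabel)
      msg <- c(msg, "classLabel inconsistent with concentration grouping")
    if (!num1(object@testContrast) || object@testContrast < 0 ||
        object@testContrast > 1)
      msg <- c(msg, "testContrast must be in [0, 1]")
    else if (num1(object@concentration) && object@concentration == 0 &&
             object@testContrast != 0)
      msg <- c(msg, "testContrast must be 0 at zero concentration")
    if (!num1(object@controlContrast) || object@controlContrast <= 0 ||
        object@controlContrast > 1)
      msg <- c(msg, "controlContrast must be in (0, 1]")
    if (!num1(object@lightingAngle) || object@lightingAngle < 0 ||
        object@lightingAngle >= 360)
      msg <- c(msg, "lightingAngle must be in [0, 360)")
    if (!num1(object@noiseSd) || object@noiseSd < 0)
      msg <- c(msg, "noiseSd must be >= 0")
    if (!num1(object@seed))
      msg <- c(msg, "seed must be a finite number")
    if (length(msg)) msg else TRUE
  })

#' Construct StripParams
#'
#' @param concentration analyte concentration in ug/mL (0, 0.25, 0.5, 0.75
#'   or 1); the class label is derived from it.
#' @param testContrast test-line contrast in `[0, 1]`; must be 0 when
#'   `concentration` is 0.
#' @param controlContrast control-line contrast in `(0, 1]`.
#' @param lightingAngle lighting-gradient direction, degrees in `[0, 360)`.
#' @param noiseSd sd of additive Gaussian pixel noise.
#' @param seed integer seed for the render.
#' @return a validated [StripParams-class] object.
#' @examples
#' stripParams(0.5, testContrast = 0.4)
#' @export
stripParams <- function(concentration, testContrast,
                        controlContrast = 0.6, lightingAngle = 0,
                        noiseSd = 0, seed = 1L) {
  new("StripParams",
      classLabel = concentrationClass(concentration),
      concentration = concentration, testContrast = testContrast,
      controlContrast = controlContrast, lightingAngle = lightingAngle,
      noiseSd = noiseSd, seed = seed)
}

setMethod("show", "StripParams", function(object) {
  cat(sprintf(
    "StripParams: %s (%.2f ug/mL) test=%.3f control=%.3f light=%.0f deg noise=%.3f seed=%d\n",
    object@classLabel, object@concentration, object@testContrast,
    object@controlContrast, object@lightingAngle, object@noiseSd,
    as.integer(object@seed)))
})

#' StripSet: an ordered, labelled collection of strip images
#'
#' The package-wide dataset container. Each record pairs an image reference
#' (an in-memory `H x W x 3` array in `[0, 1]`, or a character file path)
#' with a row of metadata: class label, analyte concentration, provenance
#' (`"real"` or `"synthetic"`) and free extra columns (seed, rotation angle,
#' ...). Row order is meaningful (QC filtering is greedy in order).
#'
#' @slot images list of image arrays or character paths, one per record.
#' @slot meta `data.frame` with at least columns `id`, `label`,
#'   `concentration`, `provenance`; one row per record.
#' @slot labelScheme active label scheme: `"three_class"`, `"binary"` or
#'   `"five_level"`.
#' @export
setClass("StripSet",
  representation(images = "list", meta = "data.frame",
                 labelScheme = "character"),
  validity = function(object) {
    msg <- character(0)
    m <- object@meta
    need <- c("id", "label", "concentration", "provenance")
    if (!all(need %in% names(m)))
      msg <- c(msg, paste("meta must contain columns:",
                          paste(need, collapse = ", ")))
    else {
      if (length(object@images) != nrow(m))
        msg <- c(msg, "length(images) must equal nrow(meta)")
      if (anyDuplicated(m$id))
        msg <- c(msg, "duplicate image ids")
      if (!all(m$provenance %in% c("real", "synthetic")))
        msg <- c(msg, "provenance must be 'real' or 'synthetic'")
      lv <- switch(object@labelScheme,
                   three_class = .CLASS_LEVELS,
                   binary = c("negative", "positive"),
                   five_level = as.character(.CONC_LEVELS),
                   NULL)
      if (is.null(lv))
        msg <- c(msg, "labelScheme must be three_class/binary/five_level")
      else if (nrow(m) && !all(m$label %in% lv))
        msg <- c(msg, sprintf("labels must be drawn from {%s}",
                              paste(lv, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a StripSet
#'
#' @param images list of `H x W x 3` arrays (or character paths for
#'   manifest-only sets).
#' @param meta data.frame with columns `id`, `label`, `concentration`,
#'   `provenance` (and any extras), one row per image.
#' @param labelScheme the active label scheme; defaults to `"three_class"`.
#' @return a validated [StripSet-class].
#' @export
stripSet <- function(images, meta, labelScheme = "three_class") {
  meta$label <- as.character(meta$label)
  meta$provenance <- as.character(meta$provenance)
  meta$id <- as.character(meta$id)
  rownames(meta) <- NULL
  new("StripSet", images = images, meta = meta, labelScheme = labelScheme)
}

setMethod("show", "StripSet", function(object) {
  m <- object@meta
  tab <- table(factor(m$provenance, levels = c("real", "synthetic")))
  cat(sprintf("StripSet of %d records (%s scheme): %d real, %d synthetic\n",
              nrow(m), object@labelScheme, tab[["real"]],
              tab[["synthetic"]]))
  if (nrow(m)) {
    cl <- table(m$label)
    cat("  per label:", paste(sprintf("%s=%d", names(cl), cl),
                              collapse = ", "), "\n")
  }
})

#' @describeIn StripSet-class number of records
#' @param x,object a `StripSet`
#' @export
setMethod("length", "StripSet", function(x) nrow(x@meta))

setGeneric("stripMeta", function(x) standardGeneric("stripMeta"))
setGeneric("stripLabels", function(x) standardGeneric("stripLabels"))
setGeneric("provenance", function(x) standardGeneric("provenance"))
setGeneric("getImage", function(x, i) standardGeneric("getImage"))

#' @describeIn StripSet-class metadata data.frame accessor
#' @export
setMethod("stripMeta", "StripSet", function(x) x@meta)

#' @describeIn StripSet-class character vector of class labels
#' @export
setMethod("stripLabels", "StripSet", function(x) x@meta$label)

#' @describeIn StripSet-class character vector of record provenance
#' @export
setMethod("provenance", "StripSet", function(x) x@meta$provenance)

#' @describeIn StripSet-class fetch the i-th image array (loads PNG paths
#'   on demand)
#' @param i record index
#' @export
setMethod("getImage", "StripSet", function(x, i) {
  img <- x@images[[i]]
  if (is.character(img)) img <- readStripPNG(img)
  img
})

#' Subset a StripSet by record index
#' @param x a `StripSet`
#' @param i integer or logical index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "StripSet", function(x, i, j, ..., drop = FALSE) {
  stripSet(x@images[i], x@meta[i, , drop = FALSE], x@labelScheme)
})

#' Concatenate StripSets (schemes must match)
#' @param x,... StripSets
#' @export
setMethod("c", "StripSet", function(x, ...) {
  rest <- list(...)
  imgs <- x@images; meta <- x@meta
  for (y in rest) {
    if (y@labelScheme != x@labelScheme)
      stop("cannot combine StripSets with different label schemes")
    imgs <- c(imgs, y@images)
    common <- union(names(meta), names(y@meta))
    for (cn in setdiff(common, names(meta))) meta[[cn]] <- NA
    ym <- y@meta
    for (cn in setdiff(common, names(ym))) ym[[cn]] <- NA
    meta <- rbind(meta[common], ym[common])
  }
  stripSet(imgs, meta, x@labelScheme)
})
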