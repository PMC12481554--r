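## Assembly of real/synthetic training mixtures, stratified hold-out
## splits, and label-scheme mapping.

#' Mix real and synthetic StripSets at a requested composition
#'
#' Two composition modes mirror the two framings of the experiments:
#'
#' * ratio mode (default): `ratio` is the fraction of real records in the
#'   output. If the two pools already satisfy it (e.g. equal sizes at the
#'   headline 1:1 mix) everything is kept; otherwise the over-represented
#'   pool is subsampled per class, seeded.
#' * absolute-count mode: `counts = c(real, synthetic)` keeps exactly
#'   those numbers of records (split evenly across classes), as in the
#'   10%/90% (300 real + 2700 synthetic) and 1%/99% compositions.
#'
#' Per-class balance and provenance are preserved; records are never
#' duplicated.
#'
#' @param real,synthetic nonempty [StripSet-class] objects with
#'   provenance `"real"` / `"synthetic"` respectively.
#' @param ratio fraction of real records in `(0, 1)` (default 0.5).
#' @param counts optional `c(nReal, nSynthetic)` switching to
#'   absolute-count mode.
#' @param seed RNG seed for subsampling.
#' @return a combined [StripSet-class] (real records first).
#' @export
mixDatasets <- function(real, synthetic, ratio = 0.5, counts = NULL,
                        seed = 1L) {
  stopifnot(is(real, "StripSet"), is(synthetic, "StripSet"))
  if (!length(real) || !length(synthetic))
    stop("both pools must be nonempty", call. = FALSE)
  classes <- sort(unique(c(stripLabels(real), stripLabels(synthetic))))
  for (cl in classes) {
    if (!any(stripLabels(real) == cl) || !any(stripLabels(synthetic) == cl))
      stop(sprintf("class '%s' absent from one pool", cl), call. = FALSE)
  }
  takePerClass <- function(ds, nTotal, seedOff) {
    labs <- stripLabels(ds)
    per <- .splitCount(nTotal, length(classes))
    idx <- integer(0)
    withSeed(childSeed(seed, seedOff), {
      for (k in seq_along(classes)) {
        pool <- which(labs == classes[k])
        if (length(pool) < per[k])
          stop(sprintf("class '%s': need %d records, pool has %d",
                       classes[k], per[k], length(pool)), call. = FALSE)
        idx <- c(idx, sort(pool[sample.int(length(pool), per[k])]))
      }
    })
    ds[idx]
  }
  if (!is.null(counts)) {
    stopifnot(length(counts) == 2L, all(counts >= 1))
    r <- takePerClass(real, as.integer(counts[1]), 1L)
    s <- takePerClass(synthetic, as.integer(counts[2]), 2L)
    return(c(r, s))
  }
  if (ratio <= 0 || ratio >= 1)
    stop("ratio must be in (0, 1)", call. = FALSE)
  nr <- length(real); ns <- length(synthetic)
  ## target the largest total consistent with the ratio and both pools
  total <- floor(min(nr / ratio, ns / (1 - ratio)))
  nReal <- round(total * ratio); nSyn <- total - nReal
  r <- if (nReal == nr) real else takePerClass(real, nReal, 1L)
  s <- if (nSyn == ns) synthetic else takePerClass(synthetic, nSyn, 2L)
  c(r, s)
}

## split n into k near-equal integers summing to n
.splitCount <- function(n, k) {
  base <- n %/% k
  out <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  out
}

#' Stratified hold-out split
#'
#' Splits per class: each class contributes `round(trainFrac * nClass)`
#' records to the training side, so the overall split deviates from
#' `trainFrac` by at most the number of classes. Train and validation are
#' disjoint and their union is the input. Seeded and reproducible.
#'
#' @param ds a [StripSet-class]; every class needs >= 2 records.
#' @param trainFrac training fraction in `(0, 1)` (default 0.8, the 80:20
#'   hold-out).
#' @param seed RNG seed.
#' @return list with [StripSet-class] elements `train` and `validation`.
#' @export
holdoutSplit <- function(ds, trainFrac = 0.8, seed = 1L) {
  stopifnot(is(ds, "StripSet"))
  if (trainFrac <= 0 || trainFrac >= 1)
    stop("trainFrac must be in (0, 1)", call. = FALSE)
  labs <- stripLabels(ds)
  trainIdx <- integer(0)
  withSeed(seed, {
    for (cl in sort(unique(labs))) {
      pool <- which(labs == cl)
      if (length(pool) < 2L)
        stop(sprintf("class '%s' has fewer than 2 records", cl),
             call. = FALSE)
      k <- round(trainFrac * length(pool))
      k <- min(max(k, 1L), length(pool) - 1L)
      trainIdx <- c(trainIdx, pool[sample.int(length(pool), k)])
    }
  })
  trainIdx <- sort(trainIdx)
  valIdx <- setdiff(seq_along(labs), trainIdx)
  list(train = ds[trainIdx], validation = ds[valIdx])
}

#' Map a StripSet onto a different label scheme
#'
#' * `three_class`: blank / low / high from the concentration grouping;
#' * `binary`: blank maps to `negative`, everything else to `positive`;
#' * `five_level`: the concentration itself becomes the label (requires
#'   concentration metadata on every record).
#'
#' @param ds a [StripSet-class].
#' @param scheme target scheme.
#' @return a relabelled [StripSet-class].
#' @examples
#' ds <- sampleStripSet(2, profile = list(height = 128, width = 16))
#' table(stripLabels(relabel(ds, "binary")))
#' @export
relabel <- function(ds, scheme = c("three_class", "binary",
                                   "five_level")) {
  scheme <- match.arg(scheme)
  stopifnot(is(ds, "StripSet"))
  m <- ds@meta
  conc <- m$concentration
  newLab <- switch(scheme,
    three_class = {
      if (anyNA(conc)) {
        ## fall back to existing three-class labels where concentration
        ## is unavailable (e.g. GAN records carry only their class)
        if (!all(m$label %in% .CLASS_LEVELS))
          stop("records lack concentration and three-class labels",
               call. = FALSE)
        m$label
      } else concentrationClass(conc)
    },
    binary = {
      base <- if (anyNA(conc)) m$label else concentrationClass(conc)
      ifelse(base == "blank", "negative", "positive")
    },
    five_level = {
      if (anyNA(conc))
        stop("five_level relabelling requires concentration metadata",
             call. = FALSE)
      as.character(conc)
    })
  m$label <- newLab
  stripSet(ds@images, m, scheme)
}
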