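## Direct spatial self-attention.
##
## Query, key and value maps are produced by 1x1 feature extractors
## (channel-mixing matrices W_f, W_g, W_v). Instead of flattening the
## feature tensor into an N x N position-by-position product, the module
## contracts query and key over channels to a single spatial score map,
## softmax-normalizes it over all positions, and rescales the value map
## pointwise:
##
##   s[h,w]  = sum_c f(x)[c,h,w] * g(x)[c,h,w]
##   M       = softmax(s) over all H*W positions
##   o[c,h,w]= (H*W) * M[h,w] * v(x)[c,h,w]
##   y       = gamma * o + x
##
## The H*W rescaling keeps the expected magnitude of o on the scale of
## v(x) (a uniform map has weight 1/(H*W) everywhere). gamma starts at
## exactly 0 so a fresh block is a bit-exact identity; it becomes nonzero
## through training. The whole forward path is pointwise products,
## channel contractions and one softmax reduction — the feature tensor is
## never reshaped or transposed, which is what makes the map directly
## interpretable as a spatial heat map.

#' AttentionBlock: learnable direct spatial self-attention state
#'
#' @slot Wf,Wg,Wv `C x C` channel-mixing matrices (1x1 feature
#'   extractors for query, key and value); spatial dimensions are
#'   untouched.
#' @slot gamma scalar residual weight, exactly 0 at construction.
#' @export
setClass("AttentionBlock",
  representation(Wf = "matrix", Wg = "matrix", Wv = "matrix",
                 gamma = "numeric"),
  validity = function(object) {
    msg <- character(0)
    dims <- lapply(list(object@Wf, object@Wg, object@Wv), dim)
    if (!all(vapply(dims, function(d) d[1] == d[2], logical(1))) ||
        length(unique(vapply(dims, paste, character(1),
                             collapse = "x"))) != 1L)
      msg <- c(msg, "Wf, Wg, Wv must be square matrices of one size")
    if (length(object@gamma) != 1L || !is.finite(object@gamma))
      msg <- c(msg, "gamma must be a finite scalar")
    if (length(msg)) msg else TRUE
  })

#' Construct a fresh attention block
#'
#' Weights are Gaussian with sd `1/sqrt(C)`; `gamma` is exactly 0, so the
#' freshly built block maps any input to itself bit-exactly.
#' @param channels number of feature channels `C`.
#' @param seed RNG seed for the weight draw.
#' @return an [AttentionBlock-class].
#' @examples
#' blk <- attentionBlock(8)
#' attentionGamma(blk)
#' @export
attentionBlock <- function(channels, seed = 1L) {
  withSeed(seed, {
    sdw <- 1 / sqrt(channels)
    new("AttentionBlock",
        Wf = matrix(rnorm(channels^2, sd = sdw), channels, channels),
        Wg = matrix(rnorm(channels^2, sd = sdw), channels, channels),
        Wv = matrix(rnorm(channels^2, sd = sdw), channels, channels),
        gamma = 0)
  })
}

setGeneric("attentionGamma", function(x) standardGeneric("attentionGamma"))

#' @describeIn AttentionBlock-class residual weight accessor
#' @param x an `AttentionBlock`
#' @export
setMethod("attentionGamma", "AttentionBlock", function(x) x@gamma)

setMethod("show", "AttentionBlock", function(object) {
  cat(sprintf("AttentionBlock: %d channels, gamma = %.6g\n",
              nrow(object@Wf), object@gamma))
})

## internal forward over a batch (N,H,W,C) given a flat param list
## (Wf, Wg, Wv, gamma); returns output, per-sample maps and caches
.attForward <- function(x, p) {
  d <- dim(x)
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  if (ncol(p$Wf) != C)
    stop(sprintf("attention block has %d channels, input has %d",
                 ncol(p$Wf), C), call. = FALSE)
  if (!all(is.finite(x)))
    stop("non-finite activations entering attention block", call. = FALSE)
  HW <- H * W
  xm <- matrix(x, nrow = N * HW, ncol = C)
  f <- xm %*% p$Wf
  g <- xm %*% p$Wg
  v <- xm %*% p$Wv
  s <- matrix(rowSums(f * g), nrow = N)          # N x HW scores
  s <- s - apply(s, 1L, max)                     # max-subtraction
  es <- exp(s)
  M <- es / rowSums(es)                          # rows sum to 1
  mVec <- as.vector(M)                           # (n fastest, then pos)
  o <- v * (HW * mVec)             # (N*HW) x C, same linear order as x
  y <- array(p$gamma * as.vector(o) + as.vector(x), dim = d)
  list(y = y, M = M, cache = list(xm = xm, f = f, g = g, v = v,
                                  mVec = mVec, o = o, d = d))
}

.attBackward <- function(dy, p, cache) {
  d <- cache$d
  N <- d[1]; HW <- d[2] * d[3]; C <- d[4]
  dym <- matrix(dy, nrow = N * HW, ncol = C)
  dgamma <- sum(dym * cache$o)
  do <- p$gamma * dym
  dv <- do * (HW * cache$mVec)
  dMvec <- HW * rowSums(do * cache$v)
  dM <- matrix(dMvec, nrow = N)
  M <- matrix(cache$mVec, nrow = N)
  ds <- M * (dM - rowSums(dM * M))               # softmax Jacobian
  dsVec <- as.vector(ds)
  df <- cache$g * dsVec
  dg <- cache$f * dsVec
  dWf <- crossprod(cache$xm, df)
  dWg <- crossprod(cache$xm, dg)
  dWv <- crossprod(cache$xm, dv)
  dxm <- df %*% t(p$Wf) + dg %*% t(p$Wg) + dv %*% t(p$Wv) + dym
  list(dx = array(dxm, dim = d), dWf = dWf, dWg = dWg, dWv = dWv,
       dgamma = dgamma)
}

.blockParams <- function(state)
  list(Wf = state@Wf, Wg = state@Wg, Wv = state@Wv, gamma = state@gamma)

#' Apply a direct self-attention block to a feature map
#'
#' Computes the softmax-normalized spatial attention map, reweights the
#' value features, and blends the result into the identity path with the
#' learnable residual weight: `y = gamma * o + x`. Output shape equals
#' input shape; with a freshly constructed block (`gamma = 0`) the output
#' equals the input bit-exactly.
#'
#' @param state an [AttentionBlock-class].
#' @param x feature map, an `H x W x C` array (finite values; `C` must
#'   match the block).
#' @return list with `y` (the `H x W x C` output) and `map` (the
#'   `H x W` attention map, non-negative, summing to 1).
#' @examples
#' blk <- attentionBlock(2)
#' x <- array(rnorm(4 * 4 * 2), dim = c(4, 4, 2))
#' identical(attentionForward(blk, x)$y, x)  # gamma = 0 identity
#' @export
attentionForward <- function(state, x) {
  stopifnot(is(state, "AttentionBlock"))
  d <- dim(x)
  if (length(d) != 3L) stop("x must be an H x W x C array", call. = FALSE)
  xb <- array(x, dim = c(1L, d))
  ## put the sample on the first axis without disturbing (h,w,c) order
  xb[1, , , ] <- x
  fw <- .attForward(xb, .blockParams(state))
  y <- array(fw$y[1, , , ], dim = d)
  list(y = y, map = matrix(fw$M[1, ], nrow = d[1], ncol = d[2]))
}

#' Spatial attention map of a feature map
#'
#' The single `H x W` map the block attends with: non-negative, sums to 1.
#' Suitable for export as a heat map ([writeAttentionMap()]).
#' @inheritParams attentionForward
#' @return `H x W` numeric matrix summing to 1.
#' @export
attentionMap <- function(state, x) attentionForward(state, x)$map

#' Export an attention map as a CSV matrix and a PNG heat map
#' @param map `H x W` matrix from [attentionMap()].
#' @param csv,pngFile output paths (`NULL` to skip either).
#' @return invisibly, the rescaled map.
#' @export
writeAttentionMap <- function(map, csv = NULL, pngFile = NULL) {
  if (!is.null(csv))
    write.csv(map, csv, row.names = FALSE)
  if (!is.null(pngFile)) {
    rng <- range(map)
    sc <- if (diff(rng) > 0) (map - rng[1]) / diff(rng) else map * 0
    png::writePNG(sc, pngFile)
  }
  invisible(map)
}

#' Number of learnable parameters of an attention block
#' @param state an [AttentionBlock-class].
#' @return integer: `3 * C^2 + 1`.
#' @export
attentionParamCount <- function(state)
  length(state@Wf) + length(state@Wg) + length(state@Wv) + 1L
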