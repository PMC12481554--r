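## Minimal neural-network engine used by the GAN and the classifier.
##
## Batches are arrays of dim c(N, H, W, C); convolutions are computed as
## im2col gathers followed by one BLAS matrix product, with exact
## hand-derived gradients. Everything is deterministic given the R RNG
## state and a single-threaded BLAS.

## ---- im2col ----------------------------------------------------------

## Index matrix [N*Ho*Wo, k*k*C] into the flattened input (0 = zero pad).
## Row order is (n fastest, then ho, then wo); column order (kh, kw, c).
im2colIndex <- function(N, H, W, C, k, stride, pad) {
  key <- sprintf("i2c:%d:%d:%d:%d:%d:%d:%d", N, H, W, C, k, stride, pad)
  .cacheGet(key, function() {
    Ho <- (H + 2L * pad - k) %/% stride + 1L
    Wo <- (W + 2L * pad - k) %/% stride + 1L
    n <- rep(seq_len(N), times = Ho * Wo)
    ho <- rep(rep(seq_len(Ho), each = N), times = Wo)
    wo <- rep(seq_len(Wo), each = N * Ho)
    R <- N * Ho * Wo
    idx <- matrix(0L, nrow = R, ncol = k * k * C)
    j <- 0L
    for (c0 in seq_len(C)) for (kw in seq_len(k)) for (kh in seq_len(k)) {
      j <- j + 1L
      h <- (ho - 1L) * stride + kh - pad
      w <- (wo - 1L) * stride + kw - pad
      ok <- h >= 1L & h <= H & w >= 1L & w <= W
      v <- integer(R)
      v[ok] <- n[ok] + N * (h[ok] - 1L) + N * H * (w[ok] - 1L) +
        N * H * W * (c0 - 1L)
      idx[, j] <- v
    }
    list(idx = idx, Ho = Ho, Wo = Wo)
  })
}

## ---- layers ----------------------------------------------------------

convForward <- function(x, W, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  d <- dim(x)
  ii <- im2colIndex(d[1], d[2], d[3], d[4], k, stride, pad)
  Xcol <- .Call(C_im2col_gather, as.double(x), ii$idx)
  out <- Xcol %*% W
  out <- out + rep(b, each = nrow(out))
  list(out = array(out, dim = c(d[1], ii$Ho, ii$Wo, ncol(W))),
       Xcol = Xcol, ii = ii, dIn = d)
}

convBackward <- function(dout, cache, W) {
  dM <- dout
  dim(dM) <- c(nrow(cache$Xcol), length(dout) %/% nrow(cache$Xcol))
  dW <- crossprod(cache$Xcol, dM)
  db <- colSums(dM)
  dXcol <- dM %*% t(W)
  dxv <- .Call(C_col2im_scatter, dXcol, cache$ii$idx,
               as.double(prod(cache$dIn)))
  list(dx = array(dxv, dim = cache$dIn), dW = dW, db = db)
}

linForward <- function(x, W, b) {
  out <- x %*% W
  out + rep(b, each = nrow(out))
}

linBackward <- function(dout, x, W) {
  list(dx = dout %*% t(W), dW = crossprod(x, dout), db = colSums(dout))
}

lrelu <- function(x, a = 0.2) {
  y <- x
  y[x < 0] <- a * x[x < 0]
  y
}

lreluBack <- function(dy, x, a = 0.2) {
  g <- dy
  g[x < 0] <- a * dy[x < 0]
  g
}

sigmoidF <- function(x) 1 / (1 + exp(-x))

upsample2 <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), ,
    drop = FALSE]
}

upsample2Back <- function(dy) {
  d <- dim(dy)
  od <- seq(1L, d[2], by = 2L); ev <- od + 1L
  odw <- seq(1L, d[3], by = 2L); evw <- odw + 1L
  dy[, od, odw, , drop = FALSE] + dy[, ev, odw, , drop = FALSE] +
    dy[, od, evw, , drop = FALSE] + dy[, ev, evw, , drop = FALSE]
}

## concat / split along the channel (4th) axis
catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1], da[2], da[3], da[4] + db[4]))
}

splitChannels <- function(x, cA) {
  d <- dim(x)
  list(x[, , , seq_len(cA), drop = FALSE],
       x[, , , (cA + 1L):d[4], drop = FALSE])
}

## ---- initialization --------------------------------------------------

initConvW <- function(k, cin, cout)
  matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
         nrow = k * k * cin, ncol = cout)

initLinW <- function(din, dout)
  matrix(rnorm(din * dout, sd = sqrt(2 / din)), nrow = din, ncol = dout)

## ---- optimizers ------------------------------------------------------

optimInit <- function(params)
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))

rmspropStep <- function(params, grads, state, lr, rho = 0.9, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$v[[nm]] <- rho * state$v[[nm]] + (1 - rho) * g * g
    params[[nm]] <- params[[nm]] - lr * g / sqrt(state$v[[nm]] + eps)
  }
  list(params = params, state = state)
}

adamStep <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mh <- state$m[[nm]] / (1 - b1^t)
    vh <- state$v[[nm]] / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

clipParams <- function(params, clip)
  lapply(params, function(p) {
    q <- pmin(pmax(p, -clip), clip)
    if (!is.null(dim(p))) dim(q) <- dim(p)
    q
  })

## stack a StripSet (or list of images) into an (N, H, W, C) batch
stackImages <- function(x, idx = NULL) {
  imgs <- if (is(x, "StripSet")) {
    if (is.null(idx)) idx <- seq_len(length(x))
    lapply(idx, function(i) getImage(x, i))
  } else x
  d <- dim(imgs[[1]])
  out <- array(0, dim = c(length(imgs), d))
  for (i in seq_along(imgs)) out[i, , , ] <- imgs[[i]]
  out
}

unstackImages <- function(batch) {
  d <- dim(batch)
  lapply(seq_len(d[1]), function(i) array(batch[i, , , ], dim = d[-1]))
}
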