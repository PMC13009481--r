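# Native network layers. Feature maps are (H, W, C) arrays; 3x3 convolutions
# use zero ("same") padding and are evaluated as im2col + GEMM so the heavy
# lifting runs in BLAS. All backward passes are hand-derived and checked
# against finite differences in the test suite.

layer_env <- new.env(parent = emptyenv())

# Cached linear indices mapping each (pixel, tap, channel) of the padded
# input to a column of the im2col matrix. Column order (tap-row fastest,
# then tap-col, then channel) matches the column-major flattening of a
# (3, 3, Cin, Cout) weight array.
im2col_idx <- function(H, W, Cin) {
  key <- paste(H, W, Cin, sep = ":")
  cached <- layer_env[[key]]
  if (!is.null(cached)) return(cached)
  p <- seq_len(H * W)
  i <- ((p - 1L) %% H) + 1L
  j <- ((p - 1L) %/% H) + 1L
  Hp <- H + 2L; Wp <- W + 2L
  idx <- integer(H * W * 9L * Cin)
  col <- 0L
  for (c in seq_len(Cin)) for (dj in 0:2) for (di in 0:2) {
    col <- col + 1L
    lin <- (i + di) + Hp * (j + dj - 1L) + Hp * Wp * (c - 1L)
    idx[((col - 1L) * H * W + 1L):(col * H * W)] <- lin
  }
  layer_env[[key]] <- idx
  idx
}

pad1 <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3]))
  xp[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- x
  xp
}

im2col <- function(x) {
  d <- dim(x)
  matrix(pad1(x)[im2col_idx(d[1], d[2], d[3])], d[1] * d[2], 9L * d[3])
}

# Same-padded 3x3 convolution. W: (3, 3, Cin, Cout) array; b: length Cout.
conv_fw <- function(x, W, b) {
  d <- dim(x); dw <- dim(W)
  cols <- im2col(x)
  out <- cols %*% matrix(W, 9L * dw[3], dw[4])
  out <- sweep(out, 2L, b, `+`)
  array(out, c(d[1], d[2], dw[4]))
}

# Backward of conv_fw. Returns gradients w.r.t. input, weights and bias.
# dX is itself a same-padded convolution of dY with the spatially flipped,
# channel-transposed kernel (the exact adjoint of zero padding + correlation).
conv_bw <- function(x, W, dY) {
  d <- dim(x); dw <- dim(W)
  dYm <- matrix(dY, d[1] * d[2], dw[4])
  dWm <- crossprod(im2col(x), dYm)
  db <- colSums(dYm)
  Wflip <- aperm(W[3:1, 3:1, , , drop = FALSE], c(1, 2, 4, 3))
  dX <- array(im2col(dY) %*% matrix(Wflip, 9L * dw[4], dw[3]),
              c(d[1], d[2], dw[3]))
  list(dX = dX, dW = array(dWm, dw), db = db)
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Channel attention: squeeze (global average pool) -> bottleneck MLP ->
# sigmoid gate per channel. p: list(W1 (Cr x C), b1, W2 (C x Cr), b2).
ca_fw <- function(x, p) {
  d <- dim(x)
  z <- colMeans(matrix(x, d[1] * d[2], d[3]))
  h <- pmax(as.vector(p$W1 %*% z + p$b1), 0)
  a <- sigmoid(as.vector(p$W2 %*% h + p$b2))
  list(out = x * rep(a, each = d[1] * d[2]), z = z, h = h, a = a)
}

ca_bw <- function(x, p, fw, dY) {
  d <- dim(x); npix <- d[1] * d[2]
  dYm <- matrix(dY, npix, d[3])
  xm <- matrix(x, npix, d[3])
  da <- colSums(dYm * xm)
  dX <- array(dYm * rep(fw$a, each = npix), d)
  ds2 <- da * fw$a * (1 - fw$a)
  dW2 <- outer(ds2, fw$h)
  db2 <- ds2
  dh <- as.vector(crossprod(p$W2, ds2)) * (fw$h > 0)
  dW1 <- outer(dh, fw$z)
  db1 <- dh
  dz <- as.vector(crossprod(p$W1, dh))
  dX <- dX + array(rep(dz / npix, each = npix), d)
  list(dX = dX, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# Pixel shuffle (sub-pixel upsampling) by factor r:
# (H, W, C r^2) -> (rH, rW, C), out[r(h-1)+dh, r(w-1)+dw, c] taken from
# channel (c-1) r^2 + (dh-1) r + dw of input pixel (h, w).
pixel_shuffle <- function(x, r = 2L) {
  d <- dim(x)
  C <- d[3] %/% (r * r)
  x6 <- array(x, c(d[1], d[2], r, r, C))     # dims: h, w, dw, dh? see below
  # channel index decomposition (column-major): ch = dw + r*(dh-1) + r^2*(c-1)
  # -> dim 3 is dw, dim 4 is dh, dim 5 is c
  y <- aperm(x6, c(4, 1, 3, 2, 5))           # dh, h, dw, w, c
  array(y, c(r * d[1], r * d[2], C))
}

pixel_shuffle_bw <- function(dY, r = 2L) {
  d <- dim(dY)
  H <- d[1] %/% r; W <- d[2] %/% r; C <- d[3]
  y <- array(dY, c(r, H, r, W, C))
  x6 <- aperm(y, c(2, 4, 3, 1, 5))
  array(x6, c(H, W, r * r * C))
}
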