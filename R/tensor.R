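# Small tensor helpers. Activations are numeric arrays (H, W, C, N).

tensor_dim <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stop("expected a rank-4 (H, W, C, N) array", call. = FALSE)
  d
}

# expand an (A, B, N) field along a new third axis of extent D
broadcast3 <- function(g, D) {
  d <- dim(g)
  aperm(array(g, c(d[1], d[2], d[3], D)), c(1, 2, 4, 3))
}

relu_fw <- function(x) x * (x > 0)
relu_bw <- function(x, dy) dy * (x > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

concat_channels <- function(a, b) {
  da <- tensor_dim(a); db <- tensor_dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2], da[4] == db[4])
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_channels <- function(x, c1) {
  d <- tensor_dim(x)
  list(x[, , seq_len(c1), , drop = FALSE],
       x[, , (c1 + 1):d[3], , drop = FALSE])
}

# Interpolation matrix for 2x bilinear upsampling along one axis, using the
# half-pixel-center convention: output index i samples input at (i + .5)/2 - .5
# with edge clamping. Returns a dense (2n x n) matrix; its transpose is the
# exact backward operator.
bilinear_matrix <- function(n) {
  A <- matrix(0, 2L * n, n)
  for (i in seq_len(2L * n)) {
    src <- (i - 1 + 0.5) / 2 - 0.5
    i0 <- floor(src)
    w1 <- src - i0
    i0c <- min(max(i0, 0), n - 1)
    i1c <- min(max(i0 + 1, 0), n - 1)
    A[i, i0c + 1] <- A[i, i0c + 1] + (1 - w1)
    A[i, i1c + 1] <- A[i, i1c + 1] + w1
  }
  A
}

upsample2_fw <- function(x) {
  d <- tensor_dim(x)
  Ah <- bilinear_matrix(d[1])
  Aw <- bilinear_matrix(d[2])
  y <- Ah %*% matrix(x, d[1], d[2] * d[3] * d[4])          # rows
  y <- array(y, c(2 * d[1], d[2], d[3], d[4]))
  y <- aperm(y, c(2, 1, 3, 4))
  y <- Aw %*% matrix(y, d[2], 2 * d[1] * d[3] * d[4])      # cols
  y <- array(y, c(2 * d[2], 2 * d[1], d[3], d[4]))
  aperm(y, c(2, 1, 3, 4))
}

upsample2_bw <- function(dy, in_dim) {
  d <- in_dim
  Ah <- bilinear_matrix(d[1])
  Aw <- bilinear_matrix(d[2])
  g <- aperm(dy, c(2, 1, 3, 4))
  g <- t(Aw) %*% matrix(g, 2 * d[2], 2 * d[1] * d[3] * d[4])
  g <- array(g, c(d[2], 2 * d[1], d[3], d[4]))
  g <- aperm(g, c(2, 1, 3, 4))
  g <- t(Ah) %*% matrix(g, 2 * d[1], d[2] * d[3] * d[4])
  array(g, d)
}

# 2x2 stride-2 transposed convolution (plain U-Net upsampling).
# w: (2, 2, c_in, c_out); y[2i+u-1, 2j+v-1, o] = sum_c x[i,j,c] w[u,v,c,o] + b[o]
convT2_fw <- function(x, w, b) {
  d <- tensor_dim(x)
  co <- dim(w)[4]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  y <- array(0, c(2 * d[1], 2 * d[2], co, d[4]))
  for (u in 1:2) for (v in 1:2) {
    wm <- matrix(w[u, v, , ], d[3], co)
    yuv <- xm %*% wm                                        # (H*W*N) x co
    yuv <- aperm(array(yuv, c(d[1], d[2], d[4], co)), c(1, 2, 4, 3))
    y[seq(u, 2 * d[1], 2), seq(v, 2 * d[2], 2), , ] <- yuv
  }
  y + array(rep(rep(b, each = 4 * d[1] * d[2]), d[4]), dim(y))
}

convT2_bw <- function(x, w, dy) {
  d <- tensor_dim(x)
  co <- dim(w)[4]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  dw <- array(0, dim(w))
  dxm <- matrix(0, d[1] * d[2] * d[4], d[3])
  for (u in 1:2) for (v in 1:2) {
    dyuv <- dy[seq(u, 2 * d[1], 2), seq(v, 2 * d[2], 2), , , drop = FALSE]
    dym <- matrix(aperm(dyuv, c(1, 2, 4, 3)), d[1] * d[2] * d[4], co)
    dw[u, v, , ] <- crossprod(xm, dym)
    dxm <- dxm + dym %*% t(matrix(w[u, v, , ], d[3], co))
  }
  db <- colSums(matrix(aperm(dy, c(1, 2, 4, 3)), 4 * d[1] * d[2] * d[4], co))
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dx, dw = dw, db = db)
}

# Kaiming/He fan-in initialisation for conv and linear weights.
he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}
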