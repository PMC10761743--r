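# Attention gate (AG) on skip connections, additive-attention form.
#
# A gating signal from the decoder and the encoder skip feature are each
# mapped by a 1x1 convolution (+ normalization) to an intermediate width
# C_int = C_skip / 2, summed, rectified, reduced to one channel by a third
# 1x1 convolution (+ normalization) and squashed with a sigmoid. The
# resulting coefficient map alpha in (0, 1) multiplies the skip feature,
# broadcast over its channels, suppressing activations in irrelevant regions.

conv1x1_fw <- function(x, W, b) {
  d <- tensor_dim(x)
  co <- ncol(W)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  ym <- xm %*% W
  ym <- ym + rep(b, each = nrow(ym))
  aperm(array(ym, c(d[1], d[2], d[4], co)), c(1, 2, 4, 3))
}

conv1x1_bw <- function(x, W, dy) {
  d <- tensor_dim(x)
  co <- ncol(W)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), d[1] * d[2] * d[4], co)
  dx <- aperm(array(dym %*% t(W), c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dW = crossprod(xm, dym), db = colSums(dym), dx = dx)
}

#' Create an attention-gate state
#'
#' @param c_skip Channels of the encoder skip feature.
#' @param c_gate Channels of the decoder gating signal.
#' @param c_int Intermediate width; defaults to `c_skip / 2`.
#' @return An object of class `ag_state`.
#' @export
ag_state <- function(c_skip, c_gate, c_int = max(1L, c_skip %/% 2L)) {
  e <- new_ag_unit(c_skip, c_gate, c_int)
  st <- list(meta = e$meta, params = e$params, buffers = e$buffers)
  class(st) <- "ag_state"
  st
}

#' Apply an attention gate
#'
#' Computes `alpha = sigmoid(psi(relu(map_skip(skip) + map_gate(gate))))` and
#' returns `skip * alpha`, with `alpha` broadcast over the skip channels.
#' `skip` and `gate` must share spatial size and sample count.
#'
#' @param state An [ag_state()].
#' @param skip,gate `(H, W, C, N)` arrays.
#' @param training Use batch statistics in the normalizations.
#' @return An array shaped like `skip`.
#' @export
ag_forward <- function(state, skip, gate, training = FALSE) {
  e <- new.env(parent = emptyenv())
  e$meta <- state$meta
  e$params <- state$params
  e$buffers <- state$buffers
  e$grads <- lapply(e$params, function(p) array(0, dim(p) %||% length(p)))
  ag_unit_fw(e, skip, gate, train = training)
}

new_ag_unit <- function(c_skip, c_gate, c_int = max(1L, c_skip %/% 2L)) {
  e <- new.env(parent = emptyenv())
  e$meta <- list(c_skip = as.integer(c_skip), c_gate = as.integer(c_gate),
                 c_int = as.integer(c_int))
  e$params <- list(
    Wx = matrix(stats::rnorm(c_skip * c_int, sd = sqrt(2 / c_skip)),
                c_skip, c_int),
    bx = rep(0, c_int), x_gamma = rep(1, c_int), x_beta = rep(0, c_int),
    Wg = matrix(stats::rnorm(c_gate * c_int, sd = sqrt(2 / c_gate)),
                c_gate, c_int),
    bg = rep(0, c_int), g_gamma = rep(1, c_int), g_beta = rep(0, c_int),
    Wp = matrix(stats::rnorm(c_int, sd = sqrt(2 / c_int)), c_int, 1L),
    bp = rep(0, 1), p_gamma = rep(1, 1), p_beta = rep(0, 1))
  e$buffers <- list(x_rmean = rep(0, c_int), x_rvar = rep(1, c_int),
                    g_rmean = rep(0, c_int), g_rvar = rep(1, c_int),
                    p_rmean = rep(0, 1), p_rvar = rep(1, 1))
  e$grads <- lapply(e$params, function(p) array(0, dim(p) %||% length(p)))
  e$type <- "ag_unit"
  e
}

ag_bn <- function(e, tag, z, train) {
  if (train) {
    s <- cpp_bn_stats(z, dim(z))
    mu <- s$mean; va <- s$var
    mom <- 0.1
    e$buffers[[paste0(tag, "_rmean")]] <-
      (1 - mom) * e$buffers[[paste0(tag, "_rmean")]] + mom * mu
    e$buffers[[paste0(tag, "_rvar")]] <-
      (1 - mom) * e$buffers[[paste0(tag, "_rvar")]] + mom * va
  } else {
    mu <- e$buffers[[paste0(tag, "_rmean")]]
    va <- e$buffers[[paste0(tag, "_rvar")]]
  }
  list(y = cpp_bn_fw(z, dim(z), mu, va, e$params[[paste0(tag, "_gamma")]],
                     e$params[[paste0(tag, "_beta")]], 1e-5),
       mu = mu, va = va)
}

ag_unit_fw <- function(e, skip, gate, train) {
  ds <- tensor_dim(skip); dg <- tensor_dim(gate)
  if (ds[1] != dg[1] || ds[2] != dg[2] || ds[4] != dg[4])
    stop("attention gate: skip and gating signal disagree in spatial size")
  zs <- conv1x1_fw(skip, e$params$Wx, e$params$bx)
  zg <- conv1x1_fw(gate, e$params$Wg, e$params$bg)
  bs <- ag_bn(e, "x", zs, train)
  bg <- ag_bn(e, "g", zg, train)
  q <- relu_fw(bs$y + bg$y)
  zp <- conv1x1_fw(q, e$params$Wp, e$params$bp)
  bp <- ag_bn(e, "p", zp, train)
  alpha <- sigmoid(bp$y)                                # (H, W, 1, N)
  a3 <- array(alpha, c(ds[1], ds[2], ds[4]))
  y <- skip * broadcast3(a3, ds[3])
  e$cache <- list(skip = skip, gate = gate, zs = zs, zg = zg, bs = bs,
                  bg = bg, q = q, zp = zp, bp = bp, a3 = a3)
  y
}

ag_unit_bw <- function(e, dy) {
  cc <- e$cache
  ds <- dim(cc$skip)
  ab <- broadcast3(cc$a3, ds[3])
  dskip <- dy * ab
  da <- array(colSums(aperm(dy * cc$skip, c(3, 1, 2, 4))),
              c(ds[1], ds[2], 1L, ds[4]))
  dzbp <- da * array(cc$a3 * (1 - cc$a3), dim(da))
  bnp <- cpp_bn_bw(cc$zp, dim(cc$zp), cc$bp$mu, cc$bp$va, e$params$p_gamma,
                   dzbp, 1e-5)
  e$grads$p_gamma <- e$grads$p_gamma + bnp$dgamma
  e$grads$p_beta <- e$grads$p_beta + bnp$dbeta
  cp <- conv1x1_bw(cc$q, e$params$Wp, bnp$dx)
  e$grads$Wp <- e$grads$Wp + cp$dW
  e$grads$bp <- e$grads$bp + cp$db
  dq <- relu_bw(cc$q, cp$dx)
  bnx <- cpp_bn_bw(cc$zs, dim(cc$zs), cc$bs$mu, cc$bs$va, e$params$x_gamma,
                   dq, 1e-5)
  e$grads$x_gamma <- e$grads$x_gamma + bnx$dgamma
  e$grads$x_beta <- e$grads$x_beta + bnx$dbeta
  cx <- conv1x1_bw(cc$skip, e$params$Wx, bnx$dx)
  e$grads$Wx <- e$grads$Wx + cx$dW
  e$grads$bx <- e$grads$bx + cx$db
  dskip <- dskip + cx$dx
  bng <- cpp_bn_bw(cc$zg, dim(cc$zg), cc$bg$mu, cc$bg$va, e$params$g_gamma,
                   dq, 1e-5)
  e$grads$g_gamma <- e$grads$g_gamma + bng$dgamma
  e$grads$g_beta <- e$grads$g_beta + bng$dbeta
  cg <- conv1x1_bw(cc$gate, e$params$Wg, bng$dx)
  e$grads$Wg <- e$grads$Wg + cg$dW
  e$grads$bg <- e$grads$bg + cg$db
  e$cache <- NULL
  list(dskip = dskip, dgate = cg$dx)
}
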