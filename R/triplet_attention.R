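# Triplet attention (TA).
#
# A near-parameter-free three-branch gate. Each branch exposes one pair of
# dimensions by permuting the (H, W, C) axes, compresses the remaining axis to
# two channels with Z-Pool (elementwise max and mean), convolves the pooled
# pair with a single 2->1 kernel, normalizes, and squashes with a sigmoid; the
# gate multiplies the (permuted) input elementwise. The three restored tensors
# are averaged with equal weight 1/3:
#   * channel-height branch: gate over the (H, C) plane, pooling W;
#   * channel-width branch: gate over the (C, W) plane, pooling H;
#   * spatial branch: gate over the (H, W) plane, pooling C.
# Each branch owns 2*k_ta^2 kernel weights plus one normalization scale/shift,
# so a module has 3 * (2*k_ta^2 + 2) trainable scalars: 300 for k_ta = 7,
# independent of the channel width.

ta_branch_new <- function(k_ta) {
  # scalars via rep() so every instance owns fresh storage (the optimizer
  # updates parameters in place)
  list(conv = he_init(c(k_ta, k_ta, 2L, 1L), fan_in = 2 * k_ta^2),
       bn_gamma = rep(1, 1), bn_beta = rep(0, 1),
       bn_rmean = rep(0, 1), bn_rvar = rep(1, 1))
}

#' Create a triplet-attention state
#'
#' Three branches (channel-height, channel-width, spatial), each holding a
#' `2 -> 1` convolution kernel of extent `k_ta` and one single-channel
#' normalization.
#'
#' @param k_ta Branch kernel extent (odd; default 7, padding `(k_ta-1)/2`).
#' @return An object of class `ta_state`.
#' @examples
#' ta_param_count(ta_state())  # 300
#' @export
ta_state <- function(k_ta = 7L) {
  stopifnot(k_ta %% 2 == 1)
  st <- list(k_ta = as.integer(k_ta),
             ch_height = ta_branch_new(k_ta),
             ch_width = ta_branch_new(k_ta),
             spatial = ta_branch_new(k_ta))
  class(st) <- "ta_state"
  st
}

#' Z-Pool: compress the leading axis to (max, mean)
#'
#' Reduces a `D0 x D1 x D2` tensor over its first axis to a `2 x D1 x D2`
#' tensor whose first channel is the elementwise maximum and second channel
#' the elementwise mean, in that order.
#'
#' @param t A rank-3 array.
#' @return A `2 x D1 x D2` array.
#' @export
z_pool <- function(t) {
  stopifnot(length(dim(t)) == 3L, dim(t)[1] >= 1L)
  d <- dim(t)
  m <- matrix(t, d[1], d[2] * d[3])
  out <- array(0, c(2L, d[2], d[3]))
  out[1L, , ] <- apply(m, 2, max)
  out[2L, , ] <- colMeans(m)
  out
}

#' Forward pass of a single TA branch
#'
#' Z-Pool over the leading axis, `2 -> 1` convolution with padding
#' `(k_ta-1)/2`, normalization (running statistics unless `training`), and
#' sigmoid. Values of the returned gate lie in (0, 1).
#'
#' @param branch One branch of a [ta_state()].
#' @param t A `D0 x D1 x D2` array (leading axis is pooled away).
#' @param k_ta Kernel extent of the branch.
#' @param training Use batch statistics for the normalization.
#' @return A `1 x D1 x D2` gate array.
#' @export
ta_branch_forward <- function(branch, t, k_ta = 7L, training = FALSE) {
  zp <- z_pool(t)
  d <- dim(zp)
  x <- array(aperm(zp, c(2, 3, 1)), c(d[2], d[3], 2L, 1L))
  z <- cpp_conv2d_fw(x, dim(x), branch$conv, k_ta, (k_ta - 1L) %/% 2L, NULL)
  if (training) {
    s <- cpp_bn_stats(z, dim(z))
    mu <- s$mean; va <- s$var
  } else {
    mu <- branch$bn_rmean; va <- branch$bn_rvar
  }
  g <- sigmoid(cpp_bn_fw(z, dim(z), mu, va, branch$bn_gamma, branch$bn_beta,
                         1e-5))
  array(aperm(g[, , 1L, 1L, drop = FALSE], c(3, 1, 2, 4)), c(1L, d[2], d[3]))
}

#' Forward pass of a full TA module
#'
#' Applies the three branch gates to a `(H, W, C, N)` feature map and averages
#' the gated tensors with equal weight 1/3. Output shape equals input shape.
#'
#' @param state A [ta_state()].
#' @param f A `(H, W, C, N)` array.
#' @param training Use batch statistics in the branch normalizations.
#' @return An array shaped like `f`.
#' @export
ta_forward <- function(state, f, training = FALSE) {
  tensor_dim(f)
  e <- ta_unit_from_state(state)
  ta_unit_fw(e, f, train = training)
}

#' Count the trainable scalars of a TA module
#'
#' `3 * (2 * k_ta^2 + 2)`, independent of feature-map shape.
#'
#' @param state A [ta_state()].
#' @return Integer scalar.
#' @export
ta_param_count <- function(state) {
  3L * (2L * state$k_ta * state$k_ta + 2L)
}

# ---- trainable TA unit (internal) -------------------------------------------

new_ta_unit <- function(k_ta = 7L) {
  e <- new.env(parent = emptyenv())
  e$meta <- list(k_ta = as.integer(k_ta))
  e$params <- list()
  e$buffers <- list()
  for (b in names(ta_modes)) {
    br <- ta_branch_new(k_ta)
    e$params[[paste0(b, "_conv")]] <- br$conv
    e$params[[paste0(b, "_gamma")]] <- br$bn_gamma
    e$params[[paste0(b, "_beta")]] <- br$bn_beta
    e$buffers[[paste0(b, "_rmean")]] <- br$bn_rmean
    e$buffers[[paste0(b, "_rvar")]] <- br$bn_rvar
  }
  e$grads <- lapply(e$params, function(p) array(0, dim(p) %||% length(p)))
  e$type <- "ta_unit"
  e
}

ta_unit_from_state <- function(state) {
  e <- new_ta_unit(state$k_ta)
  for (b in names(ta_modes)) {
    br <- state[[b]]
    e$params[[paste0(b, "_conv")]] <- br$conv
    e$params[[paste0(b, "_gamma")]] <- br$bn_gamma
    e$params[[paste0(b, "_beta")]] <- br$bn_beta
    e$buffers[[paste0(b, "_rmean")]] <- br$bn_rmean
    e$buffers[[paste0(b, "_rvar")]] <- br$bn_rvar
  }
  e
}

ta_modes <- c(spatial = 0L, ch_height = 1L, ch_width = 2L)

ta_branch_fw <- function(e, bname, x, train) {
  k_ta <- e$meta$k_ta
  mode <- ta_modes[[bname]]
  pl <- cpp_ta_pool(x, dim(x), mode)
  w <- e$params[[paste0(bname, "_conv")]]
  zc <- cpp_conv2d_fw_b(pl$zp, dim(pl$zp), w, k_ta, (k_ta - 1L) %/% 2L, NULL)
  if (train) {
    s <- cpp_bn_stats(zc, dim(zc))
    mu <- s$mean; va <- s$var
    mom <- 0.1
    e$buffers[[paste0(bname, "_rmean")]] <-
      (1 - mom) * e$buffers[[paste0(bname, "_rmean")]] + mom * mu
    e$buffers[[paste0(bname, "_rvar")]] <-
      (1 - mom) * e$buffers[[paste0(bname, "_rvar")]] + mom * va
  } else {
    mu <- e$buffers[[paste0(bname, "_rmean")]]
    va <- e$buffers[[paste0(bname, "_rvar")]]
  }
  g <- sigmoid(cpp_bn_fw(zc, dim(zc), mu, va,
                         e$params[[paste0(bname, "_gamma")]],
                         e$params[[paste0(bname, "_beta")]], 1e-5))
  y <- cpp_ta_gate_fw(x, dim(x), g, mode)
  e$cache[[bname]] <- list(argmax = pl$argmax, zp = pl$zp, zc = zc,
                           mu = mu, va = va, g = g)
  y
}

ta_branch_bw <- function(e, bname, dy) {
  cc <- e$cache[[bname]]
  x <- e$cache$x
  k_ta <- e$meta$k_ta
  mode <- ta_modes[[bname]]
  gb <- cpp_ta_gate_bw(x, dim(x), cc$g, dy, mode)
  dbn <- gb$dg * cc$g * (1 - cc$g)
  bn <- cpp_bn_bw(cc$zc, dim(cc$zc), cc$mu, cc$va,
                  e$params[[paste0(bname, "_gamma")]], dbn, 1e-5)
  e$grads[[paste0(bname, "_gamma")]] <-
    e$grads[[paste0(bname, "_gamma")]] + bn$dgamma
  e$grads[[paste0(bname, "_beta")]] <-
    e$grads[[paste0(bname, "_beta")]] + bn$dbeta
  w <- e$params[[paste0(bname, "_conv")]]
  cv <- cpp_conv2d_bw_b(cc$zp, dim(cc$zp), w, k_ta, (k_ta - 1L) %/% 2L,
                        bn$dx, TRUE, FALSE)
  e$grads[[paste0(bname, "_conv")]] <-
    e$grads[[paste0(bname, "_conv")]] + cv$dw
  gb$dx + cpp_ta_pool_bw(cv$dx, cc$argmax, dim(x), mode)
}

ta_unit_fw <- function(e, x, train) {
  e$cache <- list(x = x)
  acc <- NULL
  for (b in names(ta_modes)) {
    yb <- ta_branch_fw(e, b, x, train)
    acc <- if (is.null(acc)) yb else acc + yb
  }
  acc / 3
}

ta_unit_bw <- function(e, dy) {
  dy3 <- dy / 3
  dx <- NULL
  for (b in names(ta_modes)) {
    dxb <- ta_branch_bw(e, b, dy3)
    dx <- if (is.null(dx)) dxb else dx + dxb
  }
  e$cache <- NULL
  dx
}
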