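# Dynamic convolution decomposition (DCD).
#
# A DCD layer replaces a conventional 3x3 convolution by a per-sample kernel
#
#     W(x) = Lambda(x) W0 + P Phi(x) R^T
#
# where W0 is a static mean kernel, Lambda(x) is a diagonal channel-attention
# matrix scaling whole output-channel slices of W0, and P Phi(x) R^T is a
# low-rank dynamic residual in kernel-element space: R (k^2 x L) compresses the
# k^2 kernel elements to an L-dimensional latent space, Phi(x) (L x L) fuses
# the latent components per input, and P (C_out x L) raises the result back to
# output channels. With k = 3 the latent dimension is L = floor(k^2/2) = 4.
# The residual does not span the input-channel axis; it is broadcast uniformly
# over input channels after division by c_in, which keeps its parameter cost
# independent of c_in. Both Lambda(x) and Phi(x) are produced by a shared
# squeeze-and-excitation style hyper-branch: global average pooling, two
# bias-free rectified linear maps of width h = max(8, floor(max(c_in, c_out) /
# reduction_ratio)), and two bias-free heads. The channel gate is squashed as
# lambda = 1 + tanh(.), so zero-initialised heads give lambda = 1, Phi = 0 and
# the layer starts as a plain static convolution with W0.

#' Create the state of one dynamic-convolution-decomposition layer
#'
#' Allocates the trainable tensors of a DCD unit (static kernel `W0`,
#' dimension-raising matrix `P`, kernel-element compression matrix `R`, the
#' hyper-branch weights, and the scale/shift of the batch normalization that
#' follows the convolution). The hyper-branch heads are zero-initialised so
#' that a freshly created layer is exactly a static convolution with `W0`.
#'
#' @param c_in,c_out Input and output channel counts.
#' @param k Spatial kernel extent (odd); the latent dimension is
#'   `L = floor(k^2 / 2)`.
#' @param reduction_ratio Bottleneck ratio of the hyper-branch; the hidden
#'   width is `max(8, floor(max(c_in, c_out) / reduction_ratio))`.
#' @return An object of class `dcd_state`: a list of trainable arrays plus
#'   batch-norm running statistics.
#' @examples
#' st <- dcd_state(2, 4)
#' dcd_param_count(st)
#' @export
dcd_state <- function(c_in, c_out, k = 3L, reduction_ratio = 11L) {
  stopifnot(c_in >= 1, c_out >= 1, k %% 2 == 1)
  L <- floor(k^2 / 2)
  h <- max(8L, (max(c_in, c_out) %/% reduction_ratio))
  st <- list(
    c_in = as.integer(c_in), c_out = as.integer(c_out),
    k = as.integer(k), L = as.integer(L),
    reduction_ratio = as.integer(reduction_ratio), hidden = as.integer(h),
    W0 = he_init(c(k, k, c_in, c_out), fan_in = k * k * c_in),
    P  = matrix(stats::rnorm(c_out * L, sd = sqrt(1 / L)), c_out, L),
    R  = matrix(stats::rnorm(k^2 * L, sd = sqrt(1 / k^2)), k^2, L),
    W1 = he_init(c(c_in, h), fan_in = c_in),
    W2 = he_init(c(h, h), fan_in = h),
    Wl = matrix(0, h, c_out),       # lambda head, zero init: lambda == 1
    Wf = matrix(0, h, L * L),       # phi head,    zero init: Phi == 0
    bn_gamma = rep(1, c_out), bn_beta = rep(0, c_out),
    bn_rmean = rep(0, c_out), bn_rvar = rep(1, c_out)
  )
  class(st) <- "dcd_state"
  st
}

#' Spatial squeeze descriptor
#'
#' Global average pooling over the spatial dimensions: element `j` of the
#' result is the spatial mean of channel `j`, one row per sample.
#'
#' @param x A `(H, W, C, N)` array.
#' @return An `N x C` matrix.
#' @export
squeeze_descriptor <- function(x) {
  d <- tensor_dim(x)
  if (d[1] < 1 || d[2] < 1) stop("degenerate input: empty spatial extent")
  m <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
  t(matrix(m, d[3], d[4]))
}

#' Hyper-branch of a DCD layer
#'
#' Maps a squeezed channel descriptor to the diagonal channel gate
#' `lambda` (length `c_out`, squashed as `1 + tanh` so values lie in (0, 2)
#' with value 1 at zero pre-activation) and the unconstrained dynamic-fusion
#' matrix `Phi` (`L x L`), through a shared rectified bottleneck with two
#' linear heads.
#'
#' @param state A [dcd_state()].
#' @param descriptor An `N x c_in` matrix (or a length-`c_in` vector).
#' @return A list with `lambda` (`N x c_out`) and `phi` (`L, L, N` array).
#' @export
hyper_branch <- function(state, descriptor) {
  if (is.null(dim(descriptor))) descriptor <- matrix(descriptor, 1L)
  stopifnot(ncol(descriptor) == state$c_in, all(is.finite(descriptor)))
  a1 <- relu_fw(descriptor %*% state$W1)
  a2 <- relu_fw(a1 %*% state$W2)
  lambda <- 1 + tanh(a2 %*% state$Wl)
  phi <- a2 %*% state$Wf
  list(lambda = lambda,
       phi = array(t(phi), c(state$L, state$L, nrow(descriptor))))
}

#' Assemble the per-sample DCD kernel
#'
#' Computes `W(x) = Lambda(x) W0 + P Phi(x) R^T` for one sample: output
#' channel `o` of the result is `lambda[o] * W0[o]` plus the dynamic residual
#' row `(P Phi R^T)[o, ]` reshaped to `k x k` and broadcast over the input
#' channels after division by `c_in`.
#'
#' @param state A [dcd_state()].
#' @param lambda_diag Numeric vector of length `c_out`.
#' @param phi An `L x L` matrix.
#' @return A `(k, k, c_in, c_out)` kernel array.
#' @export
assemble_kernel <- function(state, lambda_diag, phi) {
  stopifnot(length(lambda_diag) == state$c_out,
            all(dim(phi) == c(state$L, state$L)))
  M <- state$P %*% phi %*% t(state$R)            # c_out x k^2
  k <- state$k
  kern <- state$W0 * rep(lambda_diag, each = k * k * state$c_in)
  resid <- array(t(M) / state$c_in, c(k, k, state$c_out))
  for (o in seq_len(state$c_out))
    kern[, , , o] <- kern[, , , o] + rep(resid[, , o], state$c_in)
  kern
}

# Batched dynamic residual P Phi R^T in the (k^2, c_out, N) layout used by the
# C++ core (which itself applies the 1/c_in broadcast scaling).
dcd_residual <- function(state, phi_flat) {
  N <- nrow(phi_flat)
  k2 <- state$k^2
  M <- array(0, c(k2, state$c_out, N))
  for (n in seq_len(N)) {
    Phi <- matrix(phi_flat[n, ], state$L, state$L)
    M[, , n] <- t(state$P %*% Phi %*% t(state$R))
  }
  M
}

#' Forward pass of a DCD unit
#'
#' Squeeze, hyper-branch, per-sample kernel assembly, 2-D convolution (stride
#' 1, zero padding `(k-1)/2`), then batch normalization and rectification, as
#' in the conventional convolution unit the layer replaces.
#'
#' @param state A [dcd_state()].
#' @param x A `(H, W, c_in, N)` array.
#' @param training If `TRUE`, normalize with batch statistics; otherwise with
#'   the stored running statistics.
#' @return A `(H, W, c_out, N)` array.
#' @export
dcd_forward <- function(state, x, training = FALSE) {
  d <- tensor_dim(x)
  if (d[3] != state$c_in)
    stop(sprintf("channel mismatch: input has %d channels, layer expects %d",
                 d[3], state$c_in))
  hb <- hyper_branch(state, squeeze_descriptor(x))
  phi_flat <- matrix(hb$phi, state$L^2, d[4])
  M <- dcd_residual(state, t(phi_flat))
  z <- cpp_dcd_conv_fw(x, dim(x), state$W0, t(hb$lambda), M,
                       state$k, (state$k - 1L) %/% 2L)
  if (training) {
    s <- cpp_bn_stats(z, dim(z))
    mu <- s$mean; va <- s$var
  } else {
    mu <- state$bn_rmean; va <- state$bn_rvar
  }
  relu_fw(cpp_bn_fw(z, dim(z), mu, va, state$bn_gamma, state$bn_beta, 1e-5))
}

#' Count the trainable scalars of a DCD layer
#'
#' Exact ledger over `W0`, `P`, `R`, the hyper-branch weights and the
#' batch-norm scale/shift. `W0` contributes what the replaced conventional
#' convolution's kernel contributed (the replaced convolution's bias is
#' dropped as redundant before normalization), so the layer overhead relative
#' to a conventional unit is `|P| + |R| + |hyper branch| - c_out`.
#'
#' @param state A [dcd_state()].
#' @return Integer scalar.
#' @export
dcd_param_count <- function(state) {
  length(state$W0) + length(state$P) + length(state$R) +
    length(state$W1) + length(state$W2) + length(state$Wl) +
    length(state$Wf) + length(state$bn_gamma) + length(state$bn_beta)
}

# ---- trainable DCD unit (internal) ------------------------------------------

new_dcd_unit <- function(c_in, c_out, k = 3L, reduction_ratio = 11L) {
  e <- new.env(parent = emptyenv())
  st <- dcd_state(c_in, c_out, k, reduction_ratio)
  e$meta <- st[c("c_in", "c_out", "k", "L", "reduction_ratio", "hidden")]
  e$params <- st[c("W0", "P", "R", "W1", "W2", "Wl", "Wf",
                   "bn_gamma", "bn_beta")]
  e$buffers <- st[c("bn_rmean", "bn_rvar")]
  e$grads <- lapply(e$params, function(p) array(0, dim(p) %||% length(p)))
  e$type <- "dcd_unit"
  e
}

dcd_unit_fw <- function(e, x, train) {
  p <- e$params; m <- e$meta
  pad <- (m$k - 1L) %/% 2L
  desc <- squeeze_descriptor(x)
  a1 <- relu_fw(desc %*% p$W1)
  a2 <- relu_fw(a1 %*% p$W2)
  lam <- 1 + tanh(a2 %*% p$Wl)
  phi_flat <- a2 %*% p$Wf
  st <- list(P = p$P, R = p$R, L = m$L, k = m$k,
             c_in = m$c_in, c_out = m$c_out)
  M <- dcd_residual(st, phi_flat)
  fwb <- cpp_dcd_conv_fw_b(x, dim(x), p$W0, t(lam), M, m$k, pad)
  z <- fwb$y
  if (train) {
    s <- cpp_bn_stats(z, dim(z))
    mu <- s$mean; va <- s$var
    mom <- 0.1
    e$buffers$bn_rmean <- (1 - mom) * e$buffers$bn_rmean + mom * mu
    e$buffers$bn_rvar <- (1 - mom) * e$buffers$bn_rvar + mom * va
  } else {
    mu <- e$buffers$bn_rmean; va <- e$buffers$bn_rvar
  }
  y <- cpp_bn_relu_fw(z, dim(z), mu, va, p$bn_gamma, p$bn_beta, 1e-5)
  e$cache <- list(x = x, desc = desc, a1 = a1, a2 = a2, lam = lam,
                  M = M, A = fwb$A, z = z, mu = mu, va = va, y = y)
  y
}

dcd_unit_bw <- function(e, dy) {
  p <- e$params; m <- e$meta; cc <- e$cache
  pad <- (m$k - 1L) %/% 2L
  bn <- cpp_bn_relu_bw(cc$z, dim(cc$z), cc$mu, cc$va, p$bn_gamma, dy,
                       cc$y, 1e-5)
  e$grads$bn_gamma <- e$grads$bn_gamma + bn$dgamma
  e$grads$bn_beta <- e$grads$bn_beta + bn$dbeta
  cv <- cpp_dcd_conv_bw_b(cc$x, dim(cc$x), p$W0, t(cc$lam), cc$M, cc$A,
                          m$k, pad, bn$dx, TRUE)
  e$grads$W0 <- e$grads$W0 + cv$dw0
  N <- dim(cc$x)[4]
  dlam <- t(cv$dlam)                                   # N x c_out
  dphi_flat <- matrix(0, N, m$L^2)
  for (n in seq_len(N)) {
    dMn <- t(cv$dM[, , n])                             # c_out x k^2
    Phin <- matrix(cc$a2[n, , drop = FALSE] %*% p$Wf, m$L, m$L)
    e$grads$P <- e$grads$P + dMn %*% p$R %*% t(Phin)
    e$grads$R <- e$grads$R + t(dMn) %*% p$P %*% Phin
    dphi_flat[n, ] <- as.vector(t(p$P) %*% dMn %*% p$R)
  }
  dlp <- dlam * (1 - (cc$lam - 1)^2)                   # through 1 + tanh
  e$grads$Wl <- e$grads$Wl + crossprod(cc$a2, dlp)
  e$grads$Wf <- e$grads$Wf + crossprod(cc$a2, dphi_flat)
  da2 <- relu_bw(cc$a2, dlp %*% t(p$Wl) + dphi_flat %*% t(p$Wf))
  e$grads$W2 <- e$grads$W2 + crossprod(cc$a1, da2)
  da1 <- relu_bw(cc$a1, da2 %*% t(p$W2))
  e$grads$W1 <- e$grads$W1 + crossprod(cc$desc, da1)
  ddesc <- da1 %*% t(p$W1)                             # N x c_in
  d <- dim(cc$x)
  # global-average-pool backward: every pixel of channel c in sample n
  # receives ddesc[n, c] / (H * W)
  dx <- cv$dx +
    array(rep(as.vector(t(ddesc)) / (d[1] * d[2]), each = d[1] * d[2]), d)
  e$cache <- NULL
  dx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
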