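# Trainable building blocks. A "unit" is an environment with named lists
# $params / $grads / $buffers, plus a $type used for dispatch. Forward passes
# cache what the matching backward pass needs.

# Conventional convolution unit: k x k convolution (with bias), batch
# normalization, rectification.
new_conv_unit <- function(c_in, c_out, k = 3L) {
  e <- new.env(parent = emptyenv())
  e$meta <- list(c_in = as.integer(c_in), c_out = as.integer(c_out),
                 k = as.integer(k))
  e$params <- list(W = he_init(c(k, k, c_in, c_out), fan_in = k * k * c_in),
                   b = rep(0, c_out),
                   bn_gamma = rep(1, c_out), bn_beta = rep(0, c_out))
  e$buffers <- list(bn_rmean = rep(0, c_out), bn_rvar = rep(1, c_out))
  e$grads <- lapply(e$params, function(p) array(0, dim(p) %||% length(p)))
  e$type <- "conv_unit"
  e
}

conv_unit_fw <- function(e, x, train) {
  m <- e$meta
  pad <- (m$k - 1L) %/% 2L
  z <- cpp_conv2d_fw_b(x, dim(x), e$params$W, m$k, pad, e$params$b)
  if (train) {
    s <- cpp_bn_stats(z, dim(z))
    mu <- s$mean; va <- s$var
    mom <- 0.1
    e$buffers$bn_rmean <- (1 - mom) * e$buffers$bn_rmean + mom * mu
    e$buffers$bn_rvar <- (1 - mom) * e$buffers$bn_rvar + mom * va
  } else {
    mu <- e$buffers$bn_rmean; va <- e$buffers$bn_rvar
  }
  y <- cpp_bn_relu_fw(z, dim(z), mu, va, e$params$bn_gamma,
                      e$params$bn_beta, 1e-5)
  e$cache <- list(x = x, z = z, mu = mu, va = va, y = y)
  y
}

conv_unit_bw <- function(e, dy, need_dx = TRUE) {
  m <- e$meta; cc <- e$cache
  pad <- (m$k - 1L) %/% 2L
  bn <- cpp_bn_relu_bw(cc$z, dim(cc$z), cc$mu, cc$va, e$params$bn_gamma,
                       dy, cc$y, 1e-5)
  e$grads$bn_gamma <- e$grads$bn_gamma + bn$dgamma
  e$grads$bn_beta <- e$grads$bn_beta + bn$dbeta
  cv <- cpp_conv2d_bw_b(cc$x, dim(cc$x), e$params$W, m$k, pad, bn$dx,
                        need_dx, TRUE)
  e$grads$W <- e$grads$W + cv$dw
  e$grads$b <- e$grads$b + cv$db
  e$cache <- NULL
  cv$dx
}

# 1x1 output head with bias (no normalization); the sigmoid lives in the
# network forward so the head can also expose logits for the training loss.
new_head_unit <- function(c_in, c_out = 1L) {
  e <- new.env(parent = emptyenv())
  e$meta <- list(c_in = as.integer(c_in), c_out = as.integer(c_out))
  e$params <- list(W = matrix(stats::rnorm(c_in * c_out, sd = sqrt(2 / c_in)),
                              c_in, c_out),
                   b = rep(0, c_out))
  e$buffers <- list()
  e$grads <- lapply(e$params, function(p) array(0, dim(p) %||% length(p)))
  e$type <- "head_unit"
  e
}

head_unit_fw <- function(e, x, train) {
  e$cache <- list(x = x)
  conv1x1_fw(x, e$params$W, e$params$b)
}

head_unit_bw <- function(e, dy) {
  cv <- conv1x1_bw(e$cache$x, e$params$W, dy)
  e$grads$W <- e$grads$W + cv$dW
  e$grads$b <- e$grads$b + cv$db
  e$cache <- NULL
  cv$dx
}

# 2x2 stride-2 transposed convolution with bias (plain U-Net upsampling).
new_convT_unit <- function(c_in, c_out) {
  e <- new.env(parent = emptyenv())
  e$meta <- list(c_in = as.integer(c_in), c_out = as.integer(c_out))
  e$params <- list(W = he_init(c(2L, 2L, c_in, c_out), fan_in = c_in),
                   b = rep(0, c_out))
  e$buffers <- list()
  e$grads <- lapply(e$params, function(p) array(0, dim(p) %||% length(p)))
  e$type <- "convT_unit"
  e
}

convT_unit_fw <- function(e, x, train) {
  e$cache <- list(x = x)
  convT2_fw(x, e$params$W, e$params$b)
}

convT_unit_bw <- function(e, dy) {
  cv <- convT2_bw(e$cache$x, e$params$W, dy)
  e$grads$W <- e$grads$W + cv$dw
  e$grads$b <- e$grads$b + cv$db
  e$cache <- NULL
  cv$dx
}

unit_fw <- function(e, x, train = FALSE) {
  switch(e$type,
         conv_unit = conv_unit_fw(e, x, train),
         dcd_unit = dcd_unit_fw(e, x, train),
         ta_unit = ta_unit_fw(e, x, train),
         head_unit = head_unit_fw(e, x, train),
         convT_unit = convT_unit_fw(e, x, train),
         stop("unknown unit type: ", e$type))
}

unit_bw <- function(e, dy, ...) {
  switch(e$type,
         conv_unit = conv_unit_bw(e, dy, ...),
         dcd_unit = dcd_unit_bw(e, dy),
         ta_unit = ta_unit_bw(e, dy),
         head_unit = head_unit_bw(e, dy),
         convT_unit = convT_unit_bw(e, dy),
         stop("unknown unit type: ", e$type))
}

unit_param_count <- function(e) {
  sum(vapply(e$params, length, integer(1)))
}

zero_grads <- function(units) {
  for (e in units)
    e$grads <- lapply(e$params, function(p) array(0, dim(p) %||% length(p)))
  invisible(NULL)
}
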