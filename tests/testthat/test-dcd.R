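# Dynamic convolution decomposition: spec examples, oracle equivalence and
# structural invariants.

test_that("squeeze descriptor is the spatial mean per channel", {
  x <- array(5, c(3, 3, 2, 2))
  expect_equal(squeeze_descriptor(x), matrix(5, 2, 2))
  expect_equal(squeeze_descriptor(array(0, c(4, 4, 3, 1))), matrix(0, 1, 3))
  x <- array(c(1, 2, 3, 4), c(2, 2, 1, 1))
  expect_equal(squeeze_descriptor(x), matrix(2.5, 1, 1))  # direct summation
  expect_error(squeeze_descriptor(array(0, c(0, 4, 1, 1))), "degenerate")
})

test_that("hyper-branch shapes, zero-init fixed point and matmul oracle", {
  set.seed(31)
  st <- dcd_state(3, 5)
  hb <- hyper_branch(st, matrix(rnorm(6), 2, 3))
  expect_equal(dim(hb$lambda), c(2L, 5L))
  expect_equal(dim(hb$phi), c(4L, 4L, 2L))
  # zero-initialised heads: lambda == 1 (squash centered at identity), phi == 0
  expect_equal(hb$lambda, matrix(1, 2, 5))
  expect_equal(hb$phi, array(0, c(4, 4, 2)))
  # random heads vs an explicitly coded matrix-product chain
  st$Wl <- matrix(rnorm(length(st$Wl)), nrow(st$Wl))
  st$Wf <- matrix(rnorm(length(st$Wf)), nrow(st$Wf))
  d <- matrix(rnorm(3), 1, 3)
  hb <- hyper_branch(st, d)
  a1 <- pmax(d %*% st$W1, 0)
  a2 <- pmax(a1 %*% st$W2, 0)
  expect_equal(hb$lambda, 1 + tanh(a2 %*% st$Wl), tolerance = 1e-12)
  expect_equal(as.vector(hb$phi), as.vector(a2 %*% st$Wf), tolerance = 1e-12)
})

test_that("kernel assembly follows Lambda(x) W0 + P Phi(x) R^T", {
  set.seed(7)
  st <- dcd_state(1, 2)
  # identity gate, zero fusion: the static kernel is returned unchanged
  expect_equal(assemble_kernel(st, rep(1, 2), matrix(0, 4, 4)), st$W0)
  # zero static kernel: the residual term alone
  st0 <- st; st0$W0[] <- 0
  phi <- matrix(rnorm(16), 4, 4)
  kern <- assemble_kernel(st0, runif(2), phi)
  M <- st0$P %*% phi %*% t(st0$R)
  for (o in 1:2)
    expect_equal(kern[, , 1, o], matrix(M[o, ], 3, 3), tolerance = 1e-12)
  # general case vs explicit loops
  lam <- runif(2, 0.5, 1.5)
  kern <- assemble_kernel(st, lam, phi)
  for (o in 1:2) for (u in 1:3) for (v in 1:3) {
    j <- (v - 1) * 3 + u
    expect_equal(kern[u, v, 1, o],
                 lam[o] * st$W0[u, v, 1, o] + M[o, j] / st$c_in,
                 tolerance = 1e-12)
  }
})

test_that("residual path is exactly homogeneous in Phi", {
  set.seed(8)
  st <- dcd_state(2, 3)
  phi <- matrix(rnorm(16), 4, 4)
  lam <- runif(3)
  k1 <- assemble_kernel(st, lam, phi)
  k2 <- assemble_kernel(st, lam, 2 * phi)
  base <- assemble_kernel(st, lam, matrix(0, 4, 4))
  expect_equal(k2 - base, 2 * (k1 - base), tolerance = 1e-12)
})

test_that("zero-initialised DCD unit reduces to a static convolution", {
  set.seed(12)
  for (rep in 1:5) {
    ci <- sample(1:3, 1); co <- sample(1:4, 1)
    st <- dcd_state(ci, co)
    x <- array(rnorm(6 * 6 * ci * 2), c(6, 6, ci, 2))
    hb <- hyper_branch(st, squeeze_descriptor(x))
    for (n in 1:2) {
      kern <- assemble_kernel(st, hb$lambda[n, ], hb$phi[, , n])
      expect_equal(kern, st$W0, tolerance = 1e-6)
    }
  }
})

test_that("layer convolution matches the explicit per-sample loop oracle", {
  set.seed(99)
  for (rep in 1:25) {
    ci <- sample(1:4, 1); co <- sample(1:4, 1)
    H <- sample(3:8, 1); W <- sample(3:8, 1); N <- sample(1:3, 1)
    st <- dcd_state(ci, co)
    st$Wl <- matrix(rnorm(length(st$Wl), sd = 0.5), nrow(st$Wl))
    st$Wf <- matrix(rnorm(length(st$Wf), sd = 0.5), nrow(st$Wf))
    x <- array(rnorm(H * W * ci * N), c(H, W, ci, N))
    hb <- hyper_branch(st, squeeze_descriptor(x))
    phi_flat <- matrix(hb$phi, st$L^2, N)
    M <- dtaunet:::dcd_residual(st, t(phi_flat))
    zb <- dtaunet:::cpp_dcd_conv_fw_b(x, dim(x), st$W0, t(hb$lambda), M, 3L,
                                      1L)$y
    zs <- dtaunet:::cpp_dcd_conv_fw(x, dim(x), st$W0, t(hb$lambda), M, 3L, 1L)
    # grouped/batched realization and the per-sample loop must agree exactly
    expect_equal(zb, zs, tolerance = 1e-6)
    for (n in seq_len(N)) {
      kern <- assemble_kernel(st, hb$lambda[n, ], hb$phi[, , n])
      ref <- conv2d_ref(array(x[, , , n], c(H, W, ci)), kern)
      expect_lt(max(abs(array(zb[, , , n], c(H, W, co)) - ref)), 1e-5)
    }
  }
})

test_that("no cross-sample leakage: permuting samples permutes outputs", {
  set.seed(5)
  st <- dcd_state(2, 3)
  st$Wl <- matrix(rnorm(length(st$Wl), sd = 0.5), nrow(st$Wl))
  st$Wf <- matrix(rnorm(length(st$Wf), sd = 0.5), nrow(st$Wf))
  x <- array(rnorm(5 * 5 * 2 * 4), c(5, 5, 2, 4))
  y <- dcd_forward(st, x)
  perm <- c(3, 1, 4, 2)
  y2 <- dcd_forward(st, x[, , , perm, drop = FALSE])
  expect_equal(y2, y[, , , perm, drop = FALSE], tolerance = 1e-6)
})

test_that("channel mismatch is rejected", {
  st <- dcd_state(3, 4)
  expect_error(dcd_forward(st, array(0, c(4, 4, 2, 1))), "channel mismatch")
})

test_that("parameter count equals a hand-summed ledger", {
  st <- dcd_state(64, 64, k = 3, reduction_ratio = 11)
  expect_equal(nrow(st$P) * ncol(st$P), 64 * 4)   # 256 scalars from P
  expect_equal(nrow(st$R) * ncol(st$R), 9 * 4)    # 36 scalars from R
  h <- st$hidden
  ledger <- 3 * 3 * 64 * 64 +      # W0
    64 * 4 + 9 * 4 +               # P, R
    64 * h + h * h +               # squeeze bottleneck
    h * 64 + h * 16 +              # lambda and phi heads
    2 * 64                         # normalization scale + shift
  expect_equal(dcd_param_count(st), ledger)
})
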