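# Triplet attention: Z-Pool enumeration, rotation round-trips, gating and the
# parameter ledger.

test_that("z_pool reduces the leading axis to (max, mean)", {
  t1 <- array(3.5, c(4, 2, 3))
  zp <- z_pool(t1)
  expect_equal(dim(zp), c(2L, 2L, 3L))
  expect_true(all(zp == 3.5))
  # direct enumeration: slices [1,3] and [2,0]
  t2 <- array(0, c(2, 1, 2))
  t2[1, 1, ] <- c(1, 3); t2[2, 1, ] <- c(2, 0)
  zp <- z_pool(t2)
  expect_equal(as.vector(zp[1, 1, ]), c(2, 3))      # max channel
  expect_equal(as.vector(zp[2, 1, ]), c(1.5, 1.5))  # mean channel
  # leading extent is exactly 2 regardless of D0
  for (d0 in c(1, 5, 17))
    expect_equal(dim(z_pool(array(rnorm(d0 * 6), c(d0, 3, 2))))[1], 2L)
})

test_that("branch forward has unit-channel shape and sigmoid range", {
  set.seed(3)
  st <- ta_state()
  t <- array(rnorm(5 * 6 * 7), c(5, 6, 7))
  g <- ta_branch_forward(st$spatial, t, st$k_ta)
  expect_equal(dim(g), c(1L, 6L, 7L))
  expect_true(all(g > 0 & g < 1))
})

test_that("branch forward matches the composed-operator oracle", {
  set.seed(4)
  st <- ta_state()
  br <- st$spatial
  t <- array(rnorm(3 * 6 * 5), c(3, 6, 5))
  g <- ta_branch_forward(br, t, st$k_ta)
  zp <- z_pool(t)
  x <- array(aperm(zp, c(2, 3, 1)), c(6, 5, 2, 1))
  z <- conv2d_ref(array(x, c(6, 5, 2)), br$conv, pad = 3)
  zn <- br$bn_gamma * (z - br$bn_rmean) / sqrt(br$bn_rvar + 1e-5) +
    br$bn_beta
  expect_equal(as.vector(g), as.vector(1 / (1 + exp(-zn))), tolerance = 1e-6)
})

test_that("the branch plane assignments partition the three axis pairs", {
  # each branch pools exactly one axis and gates the remaining plane; the
  # index maps are mutually inverse with the forward gating (round trip)
  set.seed(6)
  x <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
  for (mode in 0:2) {
    pl <- dtaunet:::cpp_ta_pool(x, dim(x), mode)
    d <- dim(pl$zp)
    expect_equal(d[3], 2L)
    # gating with an all-ones gate returns the input exactly
    ones <- array(1, c(d[1], d[2], 1, d[4]))
    expect_identical(dtaunet:::cpp_ta_gate_fw(x, dim(x), ones, mode), x)
    # max + mean of a constant tensor are that constant
    cst <- array(2.25, dim(x))
    zp <- dtaunet:::cpp_ta_pool(cst, dim(cst), mode)$zp
    expect_true(all(zp == 2.25))
  }
})

test_that("full module preserves shape and saturated gates give identity", {
  set.seed(11)
  for (C in c(1, 64)) {
    st <- ta_state()
    f <- array(rnorm(8 * 8 * C * 2), c(8, 8, C, 2))
    y <- ta_forward(st, f)
    expect_equal(dim(y), dim(f))
    # with gates forced to 1 (huge normalization shift saturates the sigmoid)
    for (b in c("ch_height", "ch_width", "spatial")) st[[b]]$bn_beta <- 1e4
    expect_equal(ta_forward(st, f), f, tolerance = 1e-9)
  }
})

test_that("gated output is bounded by the input for non-negative inputs", {
  set.seed(13)
  st <- ta_state()
  f <- array(abs(rnorm(8 * 8 * 4 * 2)), c(8, 8, 4, 2))
  y <- ta_forward(st, f)
  expect_true(all(y <= f + 1e-12))
  expect_true(all(y >= 0))
})

test_that("parameter count is 3(2 k^2 + 2), independent of channel width", {
  expect_equal(ta_param_count(ta_state(7)), 300L)
  expect_equal(ta_param_count(ta_state(3)), 60L)
  expect_equal(9L * ta_param_count(ta_state(7)), 2700L)  # 0.0027 M network-wide
  # trainable scalars of the unit do not depend on feature shape
  for (C in c(64, 256, 1024)) {
    e <- dtaunet:::new_ta_unit(7)
    expect_equal(sum(vapply(e$params, length, integer(1))), 300L)
  }
})
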