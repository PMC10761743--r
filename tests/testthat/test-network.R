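# Network assembly: shape arithmetic, variant factory, parameter ordering,
# checkpoint round-trip, baseline equivalence.

test_that("forward produces a probability map of the input size", {
  cfg <- small_cfg()
  net <- make_variant(variant_spec(TRUE, TRUE, TRUE, TRUE), cfg, seed = 1)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  out <- net_forward(net, x)
  expect_equal(dim(out$prob), c(32L, 32L, 1L, 2L))
  expect_true(all(out$prob > 0 & out$prob < 1))
  expect_error(net_forward(net, array(0, c(30, 32, 3, 1))), "divisible by 16")
  expect_error(net_forward(net, array(0, c(32, 32, 2, 1))), "channels")
})

test_that("encoder stages halve the spatial size four times", {
  cfg <- small_cfg()
  net <- make_variant(variant_spec(), cfg, seed = 1)
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3, 1))
  e <- x
  sizes <- integer(0)
  for (l in 1:5) {
    e <- dtaunet:::unit_fw(net$units[[sprintf("enc%d_conv1", l)]], e, FALSE)
    e <- dtaunet:::unit_fw(net$units[[sprintf("enc%d_conv2", l)]], e, FALSE)
    sizes <- c(sizes, dim(e)[1])
    expect_equal(dim(e)[3], cfg$widths[l])
    if (l < 5) e <- dtaunet:::cpp_maxpool2_fw(e, dim(e))$y
  }
  expect_equal(sizes, c(32L, 16L, 8L, 4L, 2L))
})

test_that("outputs are equivariant under batch permutation at evaluation", {
  cfg <- small_cfg()
  net <- make_variant(variant_spec(TRUE, TRUE, TRUE, TRUE), cfg, seed = 3)
  x <- array(rnorm(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  y <- net_forward(net, x)$prob
  perm <- c(4, 2, 1, 3)
  y2 <- net_forward(net, x[, , , perm, drop = FALSE])$prob
  expect_equal(y2, y[, , , perm, drop = FALSE], tolerance = 1e-5)
})

test_that("variant factory spans the ablation grid with ordered param counts", {
  cfg <- small_cfg()
  n <- vapply(dtaunet:::variant_table_specs(), function(sp)
    count_parameters(make_variant(sp, cfg, seed = 1)), integer(1))
  # monotone ordering of the ablation family
  expect_lt(n[["baseline"]], n[["ta_both"]])
  expect_lt(n[["ta_both"]], n[["dcd_both"]])
  expect_lt(n[["dcd_both"]], n[["dta_unet"]])
  # TA adds exactly 300 scalars per insertion: 5 encoder + 4 decoder scales
  expect_equal(n[["ta_encoder"]] - n[["baseline"]], 5L * 300L)
  expect_equal(n[["ta_decoder"]] - n[["baseline"]], 4L * 300L)
  expect_equal(n[["ta_both"]] - n[["baseline"]], 2700L)
  # DCD overhead is additive across encoder and decoder
  expect_equal(n[["dcd_both"]] - n[["baseline"]],
               (n[["dcd_encoder"]] - n[["baseline"]]) +
                 (n[["dcd_decoder"]] - n[["baseline"]]))
  expect_error(variant_spec(dcd_encoder = TRUE, arch = "unet"), "flags")
})

test_that("a conventional 3x3 conv unit counts kernel + bias + norm scalars", {
  e <- dtaunet:::new_conv_unit(64, 64)
  expect_equal(dtaunet:::unit_param_count(e), 36864L + 64L + 128L)
})

test_that("disabling DCD and TA reproduces the baseline parameter ledger", {
  cfg <- small_cfg()
  base <- make_variant(variant_spec(), cfg, seed = 1)
  full <- make_variant(variant_spec(TRUE, TRUE, TRUE, TRUE), cfg, seed = 1)
  for (l in 1:5) {
    nb <- dtaunet:::unit_param_count(base$units[[sprintf("enc%d_conv1", l)]])
    # static unit: kernel + bias + 2 norm scalars
    ci <- if (l == 1) cfg$in_channels else cfg$widths[l - 1]
    expect_equal(nb, 9L * ci * cfg$widths[l] + 3L * cfg$widths[l])
  }
  expect_false("enc1_ta" %in% names(base$units))
  expect_true("enc1_ta" %in% names(full$units))
})

test_that("checkpoints round-trip to identical outputs", {
  cfg <- small_cfg()
  net <- make_variant(variant_spec(TRUE, FALSE, FALSE, TRUE), cfg, seed = 5)
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3, 1))
  y <- net_forward(net, x)$prob
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  expect_identical(net_forward(net2, x)$prob, y)
  expect_identical(net2$spec, net$spec)
  f <- tempfile()
  saveRDS(list(a = 1), f)
  expect_error(load_checkpoint(f), "checkpoint")
})

test_that("plain U-Net variant forwards and uses transposed-conv upsampling", {
  cfg <- small_cfg()
  net <- make_variant(variant_spec(arch = "unet"), cfg, seed = 2)
  expect_equal(net$units[["dec4_up"]]$type, "convT_unit")
  expect_false("dec4_ag" %in% names(net$units))
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  out <- net_forward(net, x)
  expect_equal(dim(out$prob), c(32L, 32L, 1L, 2L))
})
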