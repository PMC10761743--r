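# Metric suite: closed-form cases, algebraic identities, brute-force
# Hausdorff oracle, loss minimization.

cc <- function(tp, fp, fn) structure(list(tp = tp, fp = fp, fn = fn),
                                     class = "confusion_counts")

test_that("confusion counts match per-pixel enumeration", {
  m <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(unclass(confusion(m, m))[c("tp", "fp", "fn")],
               list(tp = 2L, fp = 0L, fn = 0L))
  a <- matrix(0, 2, 2); a[1, 1] <- 1
  b <- matrix(0, 2, 2); b[2, 2] <- 1
  expect_equal(unclass(confusion(a, b))[c("tp", "fp", "fn")],
               list(tp = 0L, fp = 1L, fn = 1L))
  set.seed(41)
  p <- random_binary_mask(8); g <- random_binary_mask(8)
  r <- confusion(p, g)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in 1:8) for (j in 1:8) {
    if (p[i, j] == 1 && g[i, j] == 1) tp <- tp + 1L
    if (p[i, j] == 1 && g[i, j] == 0) fp <- fp + 1L
    if (p[i, j] == 0 && g[i, j] == 1) fn <- fn + 1L
  }
  expect_equal(c(r$tp, r$fp, r$fn), c(tp, fp, fn))
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(confusion(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("overlap metrics match their closed forms and conventions", {
  expect_equal(iou(cc(5, 0, 0)), 1)
  expect_equal(iou(cc(2, 1, 1)), 0.5)
  expect_equal(iou(cc(0, 0, 0)), 1)          # both-empty convention
  expect_equal(dsc(cc(2, 1, 1)), 2 / 3)
  expect_equal(dsc(cc(5, 0, 0)), 1)
  expect_equal(precision(cc(2, 1, 0)), 2 / 3)
  expect_equal(precision(cc(0, 3, 0)), 0)
  expect_equal(precision(cc(0, 0, 5)), 1)    # empty-prediction convention
})

test_that("DSC = 2 IoU / (1 + IoU) and 0 <= IoU <= DSC <= 1 on random counts", {
  set.seed(42)
  for (i in 1:1000) {
    r <- cc(sample(0:50, 1), sample(0:50, 1), sample(0:50, 1))
    i1 <- iou(r); d1 <- dsc(r)
    expect_equal(d1, 2 * i1 / (1 + i1), tolerance = 1e-12)
    expect_true(i1 >= 0 && i1 <= d1 && d1 <= 1)
  }
})

test_that("Hausdorff distance matches brute force over all pairs", {
  expect_equal(hausdorff(cbind(0, 0), cbind(3, 4)), 5)        # 3-4-5
  a <- cbind(c(1, 4, 2), c(0, 2, 7))
  expect_equal(hausdorff(a, a), 0)
  expect_equal(hausdorff(cbind(c(0, 10), c(0, 0)), cbind(0, 0)), 10)
  expect_equal(suppressWarnings(hausdorff(matrix(0, 0, 2), cbind(1, 1))),
               NA_real_)
  expect_warning(hausdorff(matrix(0, 0, 2), cbind(1, 1)), "undefined")
  set.seed(43)
  for (i in 1:30) {
    a <- matrix(sample(0:30, 2 * sample(1:20, 1), replace = TRUE), ncol = 2)
    b <- matrix(sample(0:30, 2 * sample(1:20, 1), replace = TRUE), ncol = 2)
    expect_equal(hausdorff(a, b), hausdorff_ref(a, b), tolerance = 1e-12)
    expect_equal(hausdorff(a, b), hausdorff(b, a))   # symmetry
  }
})

test_that("adding a point to A cannot decrease the directed distance from B", {
  set.seed(44)
  for (i in 1:20) {
    a <- matrix(sample(0:20, 2 * sample(2:10, 1), replace = TRUE), ncol = 2)
    b <- matrix(sample(0:20, 2 * sample(2:10, 1), replace = TRUE), ncol = 2)
    a2 <- rbind(a, sample(0:20, 2))
    expect_gte(dtaunet:::directed_hausdorff(a2, b) + 1e-12,
               dtaunet:::directed_hausdorff(a, b))
  }
})

test_that("binary cross-entropy matches closed forms and is minimized at p = y", {
  y <- matrix(c(1, 0), 1)
  expect_lt(bce_loss(y, y), 2e-6)                         # perfect prediction
  expect_equal(bce_loss(matrix(0.5), matrix(1)), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(matrix(c(0.8, 0.2), 1), y), -mean(c(log(0.8), log(0.8))),
               tolerance = 1e-12)
  # grid search on single-pixel cases
  grid <- seq(0.01, 0.99, by = 0.01)
  for (yy in c(0, 1)) {
    losses <- vapply(grid, function(p) bce_loss(matrix(p), matrix(yy)),
                     numeric(1))
    expect_equal(grid[which.min(losses)], if (yy == 1) 0.99 else 0.01)
  }
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(1)), "shape")
})

test_that("test-set evaluation aggregates per-image metrics by the mean", {
  set.seed(45)
  cfg <- small_cfg()
  net <- make_variant(variant_spec(), cfg, seed = 1)
  items <- make_phantom_items(3, image_size = 32, seed = 9)
  rep <- evaluate_testset(net, items, 0.5)
  expect_equal(nrow(rep$per_image), 3)
  # against a looped per-image oracle using the public pieces
  for (i in 1:3) {
    x <- dtaunet:::prepare_image(items[[i]]$image, cfg$in_channels)
    pr <- net_forward(net, x)$prob[, , 1, 1]
    pred <- (pr >= 0.5) * 1
    r <- confusion(pred, items[[i]]$mask)
    expect_equal(rep$per_image$iou[i], iou(r))
    expect_equal(rep$per_image$dsc[i], dsc(r))
  }
  expect_equal(rep$aggregate$iou, mean(rep$per_image$iou))
  expect_equal(rep$aggregate$hd, mean(rep$per_image$hd, na.rm = TRUE))
  expect_error(evaluate_testset(net, list(), 0.5), "empty")
})
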