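# Segmentation metric suite: pixel-count overlap metrics (IoU, Dice,
# precision), the Hausdorff distance between foreground point sets under the
# Euclidean norm, and the mean pixelwise binary cross-entropy loss.

#' Pixelwise confusion counts
#'
#' @param pred,gt Binary arrays of identical shape (values in \{0, 1\}).
#' @return A list with integers `tp`, `fp`, `fn` (class `confusion_counts`).
#' @export
confusion <- function(pred, gt) {
  if (!identical(dim(pred) %||% length(pred), dim(gt) %||% length(gt)))
    stop("confusion: shape mismatch between prediction and ground truth")
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1)))
    stop("confusion: masks must be binary (0/1)")
  structure(list(tp = sum(pred == 1 & gt == 1),
                 fp = sum(pred == 1 & gt == 0),
                 fn = sum(pred == 0 & gt == 1)),
            class = "confusion_counts")
}

# Empty-mask conventions, kept in one place: when both masks are empty the
# overlap metrics are perfect by definition (1); when the prediction is empty
# precision has no positive calls and is likewise 1. The Hausdorff distance
# is undefined for an empty set and is excluded from aggregation.

#' Intersection over union, `TP / (TP + FP + FN)`
#' @param c A [confusion()] result.
#' @return Numeric in \[0, 1\]; 1 when both masks are empty.
#' @export
iou <- function(c) {
  den <- c$tp + c$fp + c$fn
  if (den == 0) 1 else c$tp / den
}

#' Dice similarity coefficient, `2 TP / (2 TP + FP + FN)`
#' @inheritParams iou
#' @return Numeric in \[0, 1\]; 1 when both masks are empty.
#' @export
dsc <- function(c) {
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) 1 else 2 * c$tp / den
}

#' Precision, `TP / (TP + FP)`
#' @inheritParams iou
#' @return Numeric in \[0, 1\]; 1 when the prediction is empty.
#' @export
precision <- function(c) {
  den <- c$tp + c$fp
  if (den == 0) 1 else c$tp / den
}

#' Foreground pixel coordinates of a binary mask
#'
#' @param mask A binary matrix.
#' @return An `n x 2` integer matrix of (row, col) coordinates, 0-based.
#' @export
mask_points <- function(mask) {
  w <- which(mask == 1, arr.ind = TRUE)
  cbind(row = w[, 1] - 1L, col = w[, 2] - 1L)
}

directed_hausdorff <- function(a, b) {
  # max over a of the distance to the nearest b, Euclidean metric
  worst <- 0
  step <- 2048L
  for (s in seq(1L, nrow(a), by = step)) {
    ae <- a[s:min(nrow(a), s + step - 1L), , drop = FALSE]
    d2 <- outer(ae[, 1], b[, 1], "-")^2 + outer(ae[, 2], b[, 2], "-")^2
    worst <- max(worst, max(apply(d2, 1, min)))
  }
  sqrt(worst)
}

#' Hausdorff distance between two point sets
#'
#' `HD(A, B) = max(h(A, B), h(B, A))` with `h(A, B)` the maximum over `a` of
#' the Euclidean distance to the closest point of `B`. If either set is
#' empty the distance is undefined: `NA` is returned with a warning and such
#' cases are excluded from aggregation by [evaluate_testset()].
#'
#' @param a,b `n x 2` coordinate matrices (see [mask_points()]).
#' @return Numeric `>= 0`, or `NA` if a set is empty.
#' @export
hausdorff <- function(a, b) {
  a <- matrix(a, ncol = 2)
  b <- matrix(b, ncol = 2)
  if (nrow(a) == 0 || nrow(b) == 0) {
    warning("hausdorff: empty point set, distance undefined")
    return(NA_real_)
  }
  max(directed_hausdorff(a, b), directed_hausdorff(b, a))
}

#' Mean pixelwise binary cross-entropy
#'
#' `-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))` over all pixels of the
#' batch, with probabilities clipped to `[eps, 1 - eps]`.
#'
#' @param p Predicted probabilities in (0, 1).
#' @param y Binary labels, same shape as `p`.
#' @param eps Clipping constant (default `1e-7`).
#' @return Non-negative scalar.
#' @export
bce_loss <- function(p, y, eps = 1e-7) {
  if (!identical(dim(p) %||% length(p), dim(y) %||% length(y)))
    stop("bce_loss: shape mismatch")
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Evaluate a model over a test set
#'
#' Runs the network on each image, thresholds the probability map, and
#' computes IoU, Dice, precision and Hausdorff distance per image; aggregates
#' are unweighted means over images, with undefined Hausdorff cases skipped.
#'
#' @param model A [make_variant()] network.
#' @param dataset A list of items with elements `image` (`(H, W, C)` array or
#'   `(H, W)` matrix in \[0, 1\]) and `mask` (binary `(H, W)` matrix), e.g.
#'   from [load_manifest()], or the path of a manifest file.
#' @param threshold Binarization threshold in (0, 1), default 0.5.
#' @return A `metric_report`: list with `per_image` (data.frame) and
#'   `aggregate` (named list).
#' @export
evaluate_testset <- function(model, dataset, threshold = 0.5) {
  if (is.character(dataset)) dataset <- load_manifest(dataset)
  stopifnot(threshold > 0, threshold < 1)
  if (length(dataset) == 0) stop("evaluate_testset: empty dataset")
  rows <- lapply(seq_along(dataset), function(i) {
    item <- dataset[[i]]
    x <- prepare_image(item$image, model$cfg$in_channels)
    pr <- net_forward(model, x, train = FALSE)$prob[, , 1, 1]
    pred <- (pr >= threshold) * 1
    cc <- confusion(pred, item$mask)
    hd <- suppressWarnings(hausdorff(mask_points(pred),
                                     mask_points(item$mask)))
    data.frame(id = item$id %||% as.character(i), iou = iou(cc),
               dsc = dsc(cc), precision = precision(cc), hd = hd)
  })
  per_image <- do.call(rbind, rows)
  agg <- list(iou = mean(per_image$iou), dsc = mean(per_image$dsc),
              precision = mean(per_image$precision),
              hd = mean(per_image$hd, na.rm = TRUE),
              n_images = nrow(per_image),
              n_hd_undefined = sum(is.na(per_image$hd)),
              threshold = threshold)
  structure(list(per_image = per_image, aggregate = agg),
            class = "metric_report")
}

#' Write a metric report to CSV and JSON
#'
#' One CSV row per image (id, IoU, DSC, precision, HD) and a JSON aggregate
#' block.
#'
#' @param report A [evaluate_testset()] result.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @export
write_metric_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$per_image, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report$aggregate, json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(report)
}

#' @export
print.metric_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(
    "<metric_report> %d images | IoU %.4f  DSC %.4f  Pre %.4f  HD %.4f\n",
    a$n_images, a$iou, a$dsc, a$precision, a$hd))
  invisible(x)
}

# Replicate grayscale input to the channel count the network expects and add
# the sample axis.
prepare_image <- function(img, in_channels) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  d <- dim(img)
  if (d[3] == 1L && in_channels > 1L)
    img <- array(rep(img, in_channels), c(d[1], d[2], in_channels))
  if (dim(img)[3] != in_channels)
    stop(sprintf("image has %d channels, network expects %d", dim(img)[3],
                 in_channels))
  array(img, c(dim(img), 1L))
}
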