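# Synthetic lesion phantoms.
#
# Each phantom emulates the shared properties of the lesion datasets the
# networks target: one to three lesions whose size, shape and location vary
# widely (randomly rotated, deformed ellipses spanning small-to-large radii),
# blurred lesion boundaries (the rendered lesion intensity is Gaussian
# smoothed; the label is the exact pre-blur support), and a textured
# background (smoothed noise field plus pixel noise). Everything is
# deterministic given the spec seed.

#' Specification of a synthetic lesion phantom
#'
#' @param image_size Side length in pixels (default 256).
#' @param n_lesions Integer range (length-2) of lesion counts per image.
#' @param radius_range Ellipse semi-axis range in pixels; the default 4-60
#'   spans the small-to-large lesion regimes.
#' @param boundary_blur_sigma Gaussian sigma (pixels) smoothing the rendered
#'   lesion boundary; affects intensities only, never the label.
#' @param background_texture_scale Smoothing length (pixels) of the
#'   background noise field.
#' @param contrast Additive lesion intensity; 0 renders lesions invisible.
#' @param deform Relative amplitude bound of the low-order boundary
#'   perturbation of each ellipse.
#' @param seed Integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256L, n_lesions = c(1L, 3L),
                         radius_range = c(4, 60), boundary_blur_sigma = 2,
                         background_texture_scale = 12, contrast = 0.35,
                         deform = 0.15, seed = 1L) {
  stopifnot(image_size >= 16, length(n_lesions) == 2, n_lesions[1] >= 1,
            length(radius_range) == 2, radius_range[1] > 0)
  structure(list(image_size = as.integer(image_size),
                 n_lesions = as.integer(n_lesions),
                 radius_range = as.numeric(radius_range),
                 boundary_blur_sigma = boundary_blur_sigma,
                 background_texture_scale = background_texture_scale,
                 contrast = contrast, deform = deform,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Separable Gaussian blur with edge replication, as one banded row operator
# per axis (rows renormalized at the borders).
blur_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(3 * sigma)
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmin(pmax(i + (-r):r, 1L), n)
    for (t in seq_along(j)) B[i, j[t]] <- B[i, j[t]] + w[t]
  }
  B / rowSums(B)
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  B <- blur_matrix(nrow(m), sigma)
  Bw <- if (ncol(m) == nrow(m)) B else blur_matrix(ncol(m), sigma)
  B %*% m %*% t(Bw)
}

#' Generate one lesion phantom
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (matrix in \[0, 1\]), `mask` (binary matrix,
#'   1 = lesion, exactly the pre-blur lesion support), and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(image_size = 64, seed = 7))
#' mean(ph$mask)
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  sz <- spec$image_size
  rmax_eff <- spec$radius_range[2] * (1 + spec$deform)
  if (2 * rmax_eff + 2 > sz)
    stop(sprintf("radius range up to %.1f px too large for a %d px image",
                 spec$radius_range[2], sz))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  # textured background
  bg <- 0.35 + 0.15 * scale_field(gaussian_blur(
    matrix(stats::rnorm(sz * sz), sz), spec$background_texture_scale)) +
    matrix(stats::rnorm(sz * sz, sd = 0.02), sz)
  nles <- if (spec$n_lesions[1] == spec$n_lesions[2]) spec$n_lesions[1] else
    sample(seq(spec$n_lesions[1], spec$n_lesions[2]), 1L)
  rows <- matrix(rep(seq_len(sz), sz), sz)
  cols <- t(rows)
  mask <- matrix(0L, sz, sz)
  for (i in seq_len(nles)) {
    # one overall size (log-uniform over the radius range, so small lesions
    # are as common as large ones and areas span orders of magnitude) plus an
    # eccentricity that splits it into the two semi-axes
    size <- exp(stats::runif(1, log(spec$radius_range[1]),
                             log(spec$radius_range[2])))
    ecc <- stats::runif(1, -0.4, 0.4)
    a <- min(max(size * exp(ecc), spec$radius_range[1]), spec$radius_range[2])
    b <- min(max(size * exp(-ecc), spec$radius_range[1]),
             spec$radius_range[2])
    th <- stats::runif(1, 0, pi)
    margin <- max(a, b) * (1 + spec$deform) + 1
    cy <- stats::runif(1, margin, sz - margin)
    cx <- stats::runif(1, margin, sz - margin)
    eps <- stats::runif(3, 0, spec$deform) / (2:4)
    psi <- stats::runif(3, 0, 2 * pi)
    u <- (rows - cy) * cos(th) + (cols - cx) * sin(th)
    v <- -(rows - cy) * sin(th) + (cols - cx) * cos(th)
    s <- sqrt((u / a)^2 + (v / b)^2)
    phi <- atan2(v / b, u / a)
    rad <- 1 + eps[1] * cos(2 * phi + psi[1]) + eps[2] * cos(3 * phi + psi[2]) +
      eps[3] * cos(4 * phi + psi[3])
    mask[s <= rad] <- 1L
  }
  img <- bg + spec$contrast * gaussian_blur(mask + 0, spec$boundary_blur_sigma)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask, spec = spec)
}

scale_field <- function(m) {
  s <- stats::sd(m)
  if (s == 0) m * 0 else (m - mean(m)) / s
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` phantoms (8-bit grayscale PNG images, 0/255 PNG masks) under
#' `out_dir` plus a JSON manifest listing file paths, per-item seeds and the
#' seeded train/test split (train size `ceiling(n * split_ratio)`).
#'
#' @param n Number of phantoms (`n >= 2`).
#' @param spec A [phantom_spec()]; its seed is the master seed, item `i` uses
#'   seed `spec$seed + i`.
#' @param split_ratio Train fraction in (0, 1), default 0.8.
#' @param out_dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
generate_dataset <- function(n, spec = phantom_spec(), split_ratio = 0.8,
                             out_dir) {
  if (n < 2) stop("generate_dataset: need at least 2 phantoms")
  stopifnot(split_ratio > 0, split_ratio < 1)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  items <- vector("list", n)
  for (i in seq_len(n)) {
    si <- spec
    si$seed <- spec$seed + i
    ph <- generate_phantom(si)
    ip <- file.path("images", sprintf("img_%04d.png", i))
    mp <- file.path("masks", sprintf("mask_%04d.png", i))
    png::writePNG(round(ph$image * 255) / 255, file.path(out_dir, ip))
    png::writePNG(ph$mask + 0, file.path(out_dir, mp))
    items[[i]] <- list(id = sprintf("phantom_%04d", i), image = ip,
                       mask = mp, seed = si$seed)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  ord <- sample.int(n)
  ntr <- min(ceiling(n * split_ratio), n - 1L)
  manifest <- list(format = "dtaunet-manifest", version = 1L,
                   master_seed = spec$seed, image_size = spec$image_size,
                   split_ratio = split_ratio,
                   train = items[ord[seq_len(ntr)]],
                   test = items[ord[(ntr + 1):n]])
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Load a phantom dataset manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [generate_dataset()].
#' @param split `"test"`, `"train"` or `"all"`.
#' @return A list of items with `id`, `image` (matrix in \[0, 1\]) and `mask`
#'   (binary matrix).
#' @export
load_manifest <- function(manifest_path, split = c("test", "train", "all")) {
  split <- match.arg(split)
  man <- jsonlite::read_json(manifest_path)
  if (!identical(man$format, "dtaunet-manifest"))
    stop("not a dtaunet manifest: ", manifest_path)
  base <- dirname(manifest_path)
  items <- switch(split, test = man$test, train = man$train,
                  all = c(man$train, man$test))
  lapply(items, function(it) {
    img <- png::readPNG(file.path(base, it$image))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    msk <- png::readPNG(file.path(base, it$mask))
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    list(id = it$id, image = img, mask = (msk > 0.5) * 1L)
  })
}
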