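# Independent reference implementations used as oracles. These are written as
# plain nested loops / direct formula transcriptions and must stay independent
# of the package's fast paths.

# direct 2-D convolution of one sample with one kernel, stride 1, zero pad
conv2d_ref <- function(x, w, bias = NULL, pad = (dim(w)[1] - 1) / 2) {
  H <- dim(x)[1]; W <- dim(x)[2]; Ci <- dim(x)[3]
  k <- dim(w)[1]; Co <- dim(w)[4]
  y <- array(0, c(H, W, Co))
  for (o in seq_len(Co)) {
    for (h in seq_len(H)) for (ww in seq_len(W)) {
      acc <- 0
      for (c in seq_len(Ci)) for (u in seq_len(k)) for (v in seq_len(k)) {
        ih <- h + u - 1 - pad; iw <- ww + v - 1 - pad
        if (ih >= 1 && ih <= H && iw >= 1 && iw <= W)
          acc <- acc + x[ih, iw, c] * w[u, v, c, o]
      }
      y[h, ww, o] <- acc + if (is.null(bias)) 0 else bias[o]
    }
  }
  y
}

# directed Hausdorff by full enumeration over all pairs
hausdorff_ref <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
  h_ab <- max(apply(a, 1, function(p)
    min(sqrt((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2))))
  h_ba <- max(apply(b, 1, function(p)
    min(sqrt((a[, 1] - p[1])^2 + (a[, 2] - p[2])^2))))
  max(h_ab, h_ba)
}

random_binary_mask <- function(n, p = 0.3) {
  matrix(rbinom(n * n, 1, p), n, n)
}

# small in-memory phantom set for training tests
make_phantom_items <- function(n, image_size = 32, seed = 1,
                               radius_range = c(3, 8)) {
  sp <- phantom_spec(image_size = image_size, radius_range = radius_range,
                     background_texture_scale = 3, seed = seed)
  lapply(seq_len(n), function(i) {
    si <- sp; si$seed <- sp$seed + i
    ph <- generate_phantom(si)
    list(id = sprintf("p%03d", i), image = ph$image, mask = ph$mask)
  })
}

small_cfg <- function() network_config(widths = c(4, 8, 16, 32, 64))
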