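# Network assembly: Attention U-Net backbone, DCD/TA ablation variants, plain
# U-Net, exact parameter counting and checkpointing.
#
# Attention family (per scale s = 1..5, widths doubling from 64):
#   encoder stage: dual conv unit (conventional or DCD), optional TA, then
#   2x2 max pooling between scales;
#   decoder stage: bilinear 2x upsampling, a 3x3 conv unit halving channels
#   (always conventional), an attention gate on the skip path gated by the
#   upsampled feature, channel concatenation (skip first), a dual conv unit
#   (conventional or DCD), optional TA;
#   head: 1x1 convolution to one class + sigmoid.
# Plain U-Net: same encoder (always conventional), 2x2 transposed-convolution
# upsampling, no attention gates, no TA.

#' Describe a network variant
#'
#' The 2x2 grid of DCD/TA placement in encoder and decoder spans the ablation
#' family of the Attention U-Net backbone; `arch = "unet"` selects the plain
#' U-Net comparison model (all flags must then be `FALSE`).
#'
#' @param dcd_encoder,dcd_decoder Replace the dual 3x3 convolutions of the
#'   encoder/decoder by dynamic convolution decomposition.
#' @param ta_encoder,ta_decoder Insert triplet attention after the dual
#'   convolutions of each encoder/decoder scale.
#' @param arch `"attention_unet"` (default) or `"unet"`.
#' @return An object of class `variant_spec`.
#' @export
variant_spec <- function(dcd_encoder = FALSE, dcd_decoder = FALSE,
                         ta_encoder = FALSE, ta_decoder = FALSE,
                         arch = c("attention_unet", "unet")) {
  arch <- match.arg(arch)
  if (arch == "unet" && (dcd_encoder || dcd_decoder || ta_encoder ||
                         ta_decoder))
    stop("the plain U-Net variant takes no DCD/TA flags")
  structure(list(dcd_encoder = isTRUE(dcd_encoder),
                 dcd_decoder = isTRUE(dcd_decoder),
                 ta_encoder = isTRUE(ta_encoder),
                 ta_decoder = isTRUE(ta_decoder),
                 arch = arch),
            class = "variant_spec")
}

#' Network configuration
#'
#' @param in_channels Input channels (grayscale images are replicated to 3
#'   channels at load time so one architecture serves all modalities).
#' @param out_classes Output classes; fixed sigmoid head, default 1.
#' @param widths Channels per scale; must double strictly across 5 scales.
#' @param k Convolution kernel extent; the DCD latent dimension is
#'   `floor(k^2/2)`.
#' @param k_ta Triplet-attention kernel extent.
#' @param reduction_ratio DCD hyper-branch bottleneck ratio.
#' @return An object of class `network_config`.
#' @export
network_config <- function(in_channels = 3L, out_classes = 1L,
                           widths = c(64L, 128L, 256L, 512L, 1024L),
                           k = 3L, k_ta = 7L, reduction_ratio = 11L) {
  stopifnot(length(widths) == 5L, all(diff(log2(widths)) == 1))
  structure(list(in_channels = as.integer(in_channels),
                 out_classes = as.integer(out_classes),
                 widths = as.integer(widths), k = as.integer(k),
                 L = as.integer(floor(k^2 / 2)), k_ta = as.integer(k_ta),
                 reduction_ratio = as.integer(reduction_ratio)),
            class = "network_config")
}

conv_or_dcd <- function(use_dcd, c_in, c_out, cfg) {
  if (use_dcd) new_dcd_unit(c_in, c_out, cfg$k, cfg$reduction_ratio)
  else new_conv_unit(c_in, c_out, cfg$k)
}

#' Build a network variant
#'
#' Deterministic architecture and seeded weight initialization: conv kernels
#' are drawn fan-in-scaled, normalization scales start at 1 and shifts at 0,
#' and the DCD hyper-branch heads start at zero so every DCD layer begins as
#' the static convolution it replaces.
#'
#' @param spec A [variant_spec()].
#' @param cfg A [network_config()].
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `dta_net`.
#' @examples
#' net <- make_variant(variant_spec(), network_config(), seed = 1)
#' count_parameters(net)
#' @export
make_variant <- function(spec, cfg = network_config(), seed = 1L) {
  stopifnot(inherits(spec, "variant_spec"), inherits(cfg, "network_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  w <- cfg$widths
  units <- list()
  prev <- cfg$in_channels
  for (l in 1:5) {
    units[[sprintf("enc%d_conv1", l)]] <-
      conv_or_dcd(spec$dcd_encoder, prev, w[l], cfg)
    units[[sprintf("enc%d_conv2", l)]] <-
      conv_or_dcd(spec$dcd_encoder, w[l], w[l], cfg)
    if (spec$ta_encoder)
      units[[sprintf("enc%d_ta", l)]] <- new_ta_unit(cfg$k_ta)
    prev <- w[l]
  }
  for (j in 4:1) {
    if (spec$arch == "attention_unet") {
      units[[sprintf("dec%d_up", j)]] <- new_conv_unit(w[j + 1], w[j], cfg$k)
      units[[sprintf("dec%d_ag", j)]] <- new_ag_unit(w[j], w[j])
    } else {
      units[[sprintf("dec%d_up", j)]] <- new_convT_unit(w[j + 1], w[j])
    }
    units[[sprintf("dec%d_conv1", j)]] <-
      conv_or_dcd(spec$dcd_decoder, 2L * w[j], w[j], cfg)
    units[[sprintf("dec%d_conv2", j)]] <-
      conv_or_dcd(spec$dcd_decoder, w[j], w[j], cfg)
    if (spec$ta_decoder)
      units[[sprintf("dec%d_ta", j)]] <- new_ta_unit(cfg$k_ta)
  }
  units[["head"]] <- new_head_unit(w[1], cfg$out_classes)
  model <- new.env(parent = emptyenv())
  model$spec <- spec
  model$cfg <- cfg
  model$seed <- as.integer(seed)
  model$units <- units
  class(model) <- "dta_net"
  model
}

#' Network forward pass
#'
#' @param model A [make_variant()] network.
#' @param x A `(H, W, in_channels, N)` array; `H` and `W` must be divisible
#'   by 16 (four pooling stages).
#' @param train Use batch statistics and cache activations for a subsequent
#'   backward pass.
#' @return A list with `prob` (the `(H, W, 1, N)` sigmoid probability map)
#'   and `logits`.
#' @export
net_forward <- function(model, x, train = FALSE) {
  d <- tensor_dim(x)
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0)
    stop(sprintf(paste0("input spatial size %dx%d must be divisible by 16 ",
                        "(four 2x2 pooling stages)"), d[1], d[2]))
  if (d[3] != model$cfg$in_channels)
    stop(sprintf("input has %d channels, network expects %d",
                 d[3], model$cfg$in_channels))
  u <- model$units
  att <- model$spec$arch == "attention_unet"
  cache <- list()
  skips <- vector("list", 5L)
  e <- x
  for (l in 1:5) {
    e <- unit_fw(u[[sprintf("enc%d_conv1", l)]], e, train)
    e <- unit_fw(u[[sprintf("enc%d_conv2", l)]], e, train)
    if (model$spec$ta_encoder)
      e <- unit_fw(u[[sprintf("enc%d_ta", l)]], e, train)
    skips[[l]] <- e
    if (l < 5) {
      mp <- cpp_maxpool2_fw(e, dim(e))
      cache[[sprintf("pool%d", l)]] <- list(idx = mp$idx, dim = dim(e))
      e <- mp$y
    }
  }
  dn <- skips[[5]]
  for (j in 4:1) {
    if (att) {
      cache[[sprintf("updim%d", j)]] <- dim(dn)
      up <- upsample2_fw(dn)
      g <- unit_fw(u[[sprintf("dec%d_up", j)]], up, train)
      a <- ag_unit_fw(u[[sprintf("dec%d_ag", j)]], skips[[j]], g, train)
      dn <- concat_channels(a, g)
    } else {
      g <- unit_fw(u[[sprintf("dec%d_up", j)]], dn, train)
      dn <- concat_channels(skips[[j]], g)
    }
    dn <- unit_fw(u[[sprintf("dec%d_conv1", j)]], dn, train)
    dn <- unit_fw(u[[sprintf("dec%d_conv2", j)]], dn, train)
    if (model$spec$ta_decoder)
      dn <- unit_fw(u[[sprintf("dec%d_ta", j)]], dn, train)
  }
  logits <- unit_fw(u[["head"]], dn, train)
  if (train) model$cache <- cache
  list(prob = sigmoid(logits), logits = logits)
}

# Backward pass from the gradient w.r.t. the head logits; accumulates into
# every unit's $grads. Requires the immediately preceding net_forward(...,
# train = TRUE).
net_backward <- function(model, dlogits) {
  u <- model$units
  att <- model$spec$arch == "attention_unet"
  cache <- model$cache
  w <- model$cfg$widths
  g <- unit_bw(u[["head"]], dlogits)
  dskips <- vector("list", 5L)
  for (j in 1:4) {
    if (model$spec$ta_decoder)
      g <- unit_bw(u[[sprintf("dec%d_ta", j)]], g)
    g <- unit_bw(u[[sprintf("dec%d_conv2", j)]], g)
    g <- unit_bw(u[[sprintf("dec%d_conv1", j)]], g)
    parts <- split_channels(g, w[j])
    if (att) {
      ag <- ag_unit_bw(u[[sprintf("dec%d_ag", j)]], parts[[1]])
      dskips[[j]] <- ag$dskip
      dup <- parts[[2]] + ag$dgate
      dup <- unit_bw(u[[sprintf("dec%d_up", j)]], dup)
      g <- upsample2_bw(dup, cache[[sprintf("updim%d", j)]])
    } else {
      dskips[[j]] <- parts[[1]]
      g <- unit_bw(u[[sprintf("dec%d_up", j)]], parts[[2]])
    }
  }
  for (l in 5:1) {
    ge <- if (l == 5) g else {
      pc <- cache[[sprintf("pool%d", l)]]
      cpp_maxpool2_bw(pc$idx, g, dim(pc$idx), pc$dim[1], pc$dim[2])
    }
    ge <- ge + if (is.null(dskips[[l]])) 0 else dskips[[l]]
    if (model$spec$ta_encoder)
      ge <- unit_bw(u[[sprintf("enc%d_ta", l)]], ge)
    ge <- unit_bw(u[[sprintf("enc%d_conv2", l)]], ge)
    g <- unit_bw(u[[sprintf("enc%d_conv1", l)]], ge, need_dx = (l > 1))
  }
  invisible(NULL)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (convolution kernels and biases,
#' normalization scales and shifts, DCD stores and hyper-branches, TA branch
#' kernels, attention-gate maps). Running statistics are buffers, not
#' parameters.
#'
#' @param model A [make_variant()] network.
#' @return Integer scalar.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$units, unit_param_count, integer(1)))
}

#' Parameter count in printed-table units
#'
#' Divides by 1e6 and rounds to 4 decimals, the tables' reporting convention.
#'
#' @param n Parameter count (or a model, which is counted first).
#' @return Numeric scalar in millions.
#' @export
params_millions <- function(n) {
  if (inherits(n, "dta_net")) n <- count_parameters(n)
  round(n / 1e6, 4)
}

#' @export
print.dta_net <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<dta_net> arch=%s dcd(enc=%s,dec=%s) ta(enc=%s,dec=%s)\n",
              s$arch, s$dcd_encoder, s$dcd_decoder, s$ta_encoder,
              s$ta_decoder))
  cat(sprintf("  widths: %s | params: %s (%.4f M)\n",
              paste(x$cfg$widths, collapse = "-"),
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  invisible(x)
}

#' Save a network checkpoint
#'
#' Serializes all named trainable tensors and buffers together with the
#' variant description, configuration and initialization seed (format
#' version 1).
#'
#' @param model A [make_variant()] network.
#' @param path Destination file.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(format = "dtaunet-checkpoint", version = 1L,
              spec = model$spec, cfg = model$cfg, seed = model$seed,
              params = lapply(model$units, function(e) e$params),
              buffers = lapply(model$units, function(e) e$buffers))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return A [make_variant()] network with the stored weights.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "dtaunet-checkpoint"))
    stop("not a dtaunet checkpoint: ", path)
  model <- make_variant(obj$spec, obj$cfg, obj$seed)
  for (nm in names(obj$params)) {
    model$units[[nm]]$params <- obj$params[[nm]]
    model$units[[nm]]$buffers <- obj$buffers[[nm]]
  }
  model
}

# The ablation grid: 8 rows (2x2 DCD/TA placement on the attention backbone)
# plus the plain U-Net comparison model.
variant_table_specs <- function() {
  list(
    baseline = variant_spec(),
    dcd_encoder = variant_spec(dcd_encoder = TRUE),
    dcd_decoder = variant_spec(dcd_decoder = TRUE),
    dcd_both = variant_spec(dcd_encoder = TRUE, dcd_decoder = TRUE),
    ta_encoder = variant_spec(ta_encoder = TRUE),
    ta_decoder = variant_spec(ta_decoder = TRUE),
    ta_both = variant_spec(ta_encoder = TRUE, ta_decoder = TRUE),
    dta_unet = variant_spec(TRUE, TRUE, TRUE, TRUE),
    unet = variant_spec(arch = "unet")
  )
}
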