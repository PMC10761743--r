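# Training and evaluation pipeline: Adam on mean pixelwise binary
# cross-entropy, seeded shuffling, per-epoch loss logging, best/final
# checkpoints, and the ablation table over all network variants.

#' Training configuration
#'
#' Defaults follow the reference protocol for this model family: Adam with
#' learning rate 0.001 (beta = (0.9, 0.999), eps = 1e-8), batch size 12,
#' binary cross-entropy loss, binarization threshold 0.5, no learning-rate
#' schedule, no augmentation, no early stopping.
#'
#' @param epochs Number of epochs.
#' @param batch_size Minibatch size (default 12).
#' @param learning_rate Adam step size (default 0.001).
#' @param beta1,beta2,eps Adam moment decays and stabilizer.
#' @param threshold Binarization threshold for evaluation.
#' @param seed Seed controlling shuffling (and any other training
#'   randomness).
#' @param checkpoint_dir,log_dir Optional output directories.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs, batch_size = 12L, learning_rate = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         threshold = 0.5, seed = 1L, checkpoint_dir = NULL,
                         log_dir = NULL) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 eps = eps, threshold = threshold, seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir, log_dir = log_dir),
            class = "train_config")
}

adam_new <- function(model) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in names(model$units)) {
    e <- model$units[[nm]]
    # the update writes through parameter storage in place: give this model
    # private copies so no other object can share the underlying memory
    e$params <- lapply(e$params, function(p) p + 0)
    ps <- e$params
    st$m[[nm]] <- lapply(ps, function(p) array(0, dim(p) %||% length(p)))
    st$v[[nm]] <- lapply(ps, function(p) array(0, dim(p) %||% length(p)))
  }
  st
}

adam_step <- function(model, opt, cfg) {
  opt$t <- opt$t + 1L
  c1 <- 1 - cfg$beta1^opt$t
  c2 <- 1 - cfg$beta2^opt$t
  for (nm in names(model$units)) {
    e <- model$units[[nm]]
    for (pn in names(e$params)) {
      # fused in-place update on storage owned by the model and optimizer
      cpp_adam_update(e$params[[pn]], e$grads[[pn]], opt$m[[nm]][[pn]],
                      opt$v[[nm]][[pn]], cfg$learning_rate, cfg$beta1,
                      cfg$beta2, cfg$eps, c1, c2)
    }
  }
  opt
}

stack_items <- function(items, in_channels) {
  xs <- lapply(items, function(it) prepare_image(it$image, in_channels))
  d <- dim(xs[[1]])
  x <- array(0, c(d[1], d[2], d[3], length(xs)))
  y <- array(0, c(d[1], d[2], 1L, length(xs)))
  for (i in seq_along(xs)) {
    x[, , , i] <- xs[[i]]
    y[, , 1L, i] <- items[[i]]$mask
  }
  list(x = x, y = y)
}

#' Train a network
#'
#' Runs `epochs` passes of seeded shuffling, minibatch forward, mean
#' pixelwise binary cross-entropy, and an Adam step. The per-epoch mean loss
#' is logged (and written to `loss.csv` under `log_dir` if set); the best
#' (lowest-loss) and final checkpoints are written under `checkpoint_dir` if
#' set. Fully reproducible given the configuration seed.
#'
#' @param model A [make_variant()] network (updated in place).
#' @param train_data A manifest path (its train split is used) or a list of
#'   items with `image` and `mask`.
#' @param cfg A [train_config()].
#' @return A list with the trained `model`, the per-epoch `history`
#'   data.frame, `best_epoch`, and checkpoint paths (if written).
#' @export
train <- function(model, train_data, cfg) {
  stopifnot(inherits(cfg, "train_config"))
  if (is.character(train_data)) train_data <- load_manifest(train_data,
                                                            "train")
  n <- length(train_data)
  if (n == 0) stop("train: empty training set")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  opt <- adam_new(model)
  history <- numeric(cfg$epochs)
  best <- Inf; best_epoch <- NA_integer_
  best_path <- final_path <- NULL
  if (!is.null(cfg$checkpoint_dir))
    dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_pix <- 0
    starts <- seq(1L, n, by = cfg$batch_size)
    for (bi in seq_along(starts)) {
      take <- ord[starts[bi]:min(n, starts[bi] + cfg$batch_size - 1L)]
      ba <- stack_items(train_data[take], model$cfg$in_channels)
      zero_grads(model$units)
      out <- net_forward(model, ba$x, train = TRUE)
      loss <- bce_loss(out$prob, ba$y)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d, batch %d: aborting",
                     ep, bi))
      npix <- length(ba$y)
      net_backward(model, (out$prob - ba$y) / npix)
      opt <- adam_step(model, opt, cfg)
      ep_loss <- ep_loss + loss * npix
      ep_pix <- ep_pix + npix
    }
    history[ep] <- ep_loss / ep_pix
    if (history[ep] < best) {
      best <- history[ep]; best_epoch <- ep
      if (!is.null(cfg$checkpoint_dir)) {
        best_path <- file.path(cfg$checkpoint_dir, "best.rds")
        save_checkpoint(model, best_path)
      }
    }
  }
  if (!is.null(cfg$checkpoint_dir)) {
    final_path <- file.path(cfg$checkpoint_dir, "final.rds")
    save_checkpoint(model, final_path)
  }
  hist_df <- data.frame(epoch = seq_len(cfg$epochs), loss = history)
  if (!is.null(cfg$log_dir)) {
    dir.create(cfg$log_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cbind(hist_df, seed = cfg$seed),
                     file.path(cfg$log_dir, "loss.csv"), row.names = FALSE)
  }
  list(model = model, history = hist_df, best_epoch = best_epoch,
       best_checkpoint = best_path, final_checkpoint = final_path)
}

#' Evaluate a checkpoint on a test set
#'
#' @param checkpoint A checkpoint path (see [save_checkpoint()]) or a
#'   network.
#' @param test_data A manifest path (its test split is used) or a list of
#'   items.
#' @param threshold Binarization threshold.
#' @param csv_path,json_path Optional report outputs (see
#'   [write_metric_report()]).
#' @return A `metric_report`.
#' @export
evaluate <- function(checkpoint, test_data, threshold = 0.5,
                     csv_path = NULL, json_path = NULL) {
  model <- if (inherits(checkpoint, "dta_net")) checkpoint else
    load_checkpoint(checkpoint)
  if (is.character(test_data)) test_data <- load_manifest(test_data, "test")
  rep <- evaluate_testset(model, test_data, threshold)
  write_metric_report(rep, csv_path, json_path)
  rep
}

#' Ablation table over all network variants
#'
#' Instantiates the eight DCD/TA placement variants of the attention backbone
#' plus the plain U-Net, counts trainable parameters exactly, and reports
#' `Params(M)` to 4 decimals with deltas versus the baseline in the
#' `(+ x.xxxx)` style.
#'
#' @param cfg A [network_config()].
#' @param seed Initialization seed (the counts do not depend on it).
#' @param tsv_path Optional path for a TSV copy of the table.
#' @return A data.frame, one row per variant.
#' @export
ablation_table <- function(cfg = network_config(), seed = 1L,
                           tsv_path = NULL) {
  specs <- variant_table_specs()
  rows <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    n <- count_parameters(make_variant(sp, cfg, seed))
    data.frame(variant = nm, arch = sp$arch,
               dcd_encoder = sp$dcd_encoder, dcd_decoder = sp$dcd_decoder,
               ta_encoder = sp$ta_encoder, ta_decoder = sp$ta_decoder,
               params = n, params_M = sprintf("%.4f", n / 1e6))
  })
  tab <- do.call(rbind, rows)
  # deltas follow the tables' convention: differences of the rounded
  # millions figures
  base <- round(tab$params[tab$variant == "baseline"] / 1e6, 4)
  d <- round(round(tab$params / 1e6, 4) - base, 4)
  tab$delta_M <- ifelse(tab$variant == "baseline", "",
                        sprintf("(%s %.4f)", ifelse(d >= 0, "+", "-"),
                                abs(d)))
  if (!is.null(tsv_path))
    utils::write.table(tab, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  tab
}
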