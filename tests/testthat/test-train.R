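# Training pipeline: reproducibility, logging, checkpoints, evaluation
# plumbing and the ablation table format.

test_that("one epoch trains, logs one loss value and writes checkpoints", {
  items <- make_phantom_items(2, seed = 51)
  cfg <- small_cfg()
  net <- make_variant(variant_spec(), cfg, seed = 1)
  ckdir <- file.path(tempdir(), "ck1")
  logdir <- file.path(tempdir(), "log1")
  res <- train(net, items, train_config(epochs = 1, batch_size = 2, seed = 2,
                                        checkpoint_dir = ckdir,
                                        log_dir = logdir))
  expect_equal(nrow(res$history), 1)
  expect_true(file.exists(res$final_checkpoint))
  expect_true(file.exists(res$best_checkpoint))
  logs <- read.csv(file.path(logdir, "loss.csv"))
  expect_equal(logs$seed, 2)
  expect_error(train(net, list(), train_config(1)), "empty")
})

test_that("a fixed seed reproduces the loss history exactly", {
  items <- make_phantom_items(4, seed = 52)
  cfg <- small_cfg()
  run <- function() {
    net <- make_variant(variant_spec(TRUE, TRUE, TRUE, TRUE), cfg, seed = 6)
    train(net, items, train_config(epochs = 3, batch_size = 3,
                                   seed = 8))$history$loss
  }
  expect_identical(run(), run())
})

test_that("evaluation of a checkpoint is idempotent and row-complete", {
  items <- make_phantom_items(3, seed = 53)
  cfg <- small_cfg()
  net <- make_variant(variant_spec(), cfg, seed = 4)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(net, ck)
  csv <- tempfile(fileext = ".csv")
  r1 <- evaluate(ck, items, 0.5, csv_path = csv)
  r2 <- evaluate(ck, items, 0.5)
  expect_identical(r1$per_image, r2$per_image)
  expect_equal(nrow(r1$per_image), length(items))
  expect_equal(nrow(read.csv(csv)), length(items))
})

test_that("the ablation table covers all variants with formatted deltas", {
  cfg <- small_cfg()
  tsv <- tempfile(fileext = ".tsv")
  tab <- ablation_table(cfg, seed = 1, tsv_path = tsv)
  expect_equal(nrow(tab), 9)
  expect_equal(tab$delta_M[tab$variant == "baseline"], "")
  d <- round(tab$params[tab$variant == "dta_unet"] / 1e6, 4) -
    round(tab$params[tab$variant == "baseline"] / 1e6, 4)
  expect_equal(tab$delta_M[tab$variant == "dta_unet"],
               sprintf("(+ %.4f)", d))
  expect_true(all(grepl("^[0-9]+\\.[0-9]{4}$", tab$params_M)))
  expect_true(file.exists(tsv))
})
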