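train_pairs <- function(seeds, size = 32) {
  lapply(seeds, function(s) {
    jit <- withr::with_seed(s, round(stats::runif(2, -3, 3)))
    cfg <- phantom_config(image_size = c(size, size), n_frames = 4,
                          semi_axes = c(8, 5), center = c(size / 2, size / 2) + jit,
                          orientation = withr::with_seed(s + 1, stats::runif(1, -0.5, 0.5)),
                          t0 = 1, beta_t = 1.5, notch_depth = 0.3,
                          noise_var = 0.01, seed = s)
    sq <- make_dce_sequence(cfg)
    list(image = sq$frames[[3]], mask = sq$truth)
  })
}

test_that("the architecture description preserves spatial size and ends in a sigmoid", {
  cfg <- cnn_config("unt", depth = 4, base_filters = 64, input_size = c(256, 256))
  md <- build_model(cfg)
  out <- md[md$layer == "output", ]
  expect_equal(c(out$out_rows, out$out_cols, out$out_channels), c(256, 256, 1))
  expect_equal(out$type, "conv1x1_sigmoid")
  # encoder halves the grid and doubles the channels per level
  pools <- md[md$type == "maxpool2x2", ]
  expect_equal(pools$out_rows, c(128, 64, 32, 16))
  expect_equal(pools$out_channels, c(64, 128, 256, 512))
})

test_that("the dense variant carries three densely connected stages and recurrent skip fusion", {
  cfg <- cnn_config("bcd_unt", depth = 3, base_filters = 8, input_size = c(64, 64))
  md <- build_model(cfg)
  expect_equal(sum(md$type == "conv3x3_relu_dense"), 3)
  expect_equal(sum(md$type == "bconvlstm_fuse"), 3) # one fusion per decoder level
  expect_equal(sum(md$type == "skip_concat"), 0)
})

test_that("input sizes not divisible by the pooling factor are rejected", {
  cfg <- cnn_config("unt", depth = 4, input_size = c(250, 250))
  expect_error(build_model(cfg), "not divisible")
})

test_that("training is seeded and reduces the validation loss on separable phantoms", {
  train <- train_pairs(1:16)
  val <- train_pairs(101:106)
  cfg <- cnn_config(depth = 2, base_filters = 4, epochs = 4, batch_size = 4,
                    input_size = c(32, 32), initial_learning_rate = 3e-3, seed = 2)
  m1 <- train_provider(train, val, cfg)
  m2 <- train_provider(train, val, cfg)
  expect_identical(m1$curves$train_loss[1], m2$curves$train_loss[1])
  expect_identical(m1$curves$val_loss, m2$curves$val_loss)
  expect_lt(tail(m1$curves$val_loss, 1), m1$curves$val_loss[1])
  p <- predict_provider(m1, val[[1]]$image)
  expect_s3_class(p, "probability_map")
  expect_true(all(p$p_kidney >= 0 & p$p_kidney <= 1))
})

test_that("degenerate training configurations are rejected", {
  pairs <- train_pairs(1:2)
  cfg <- cnn_config(depth = 2, input_size = c(32, 32))
  expect_error(train_provider(list(), pairs, cfg), "empty")
  expect_error(train_provider(pairs, list(), cfg), "empty")
  expect_error(train_provider(pairs, pairs,
                              cnn_config("bcd_unt", input_size = c(32, 32))),
               "unt")
  expect_error(cnn_config(dropout = 1), "dropout")
  expect_error(cnn_config(initial_learning_rate = 0), "positive")
})

test_that("a trained provider survives serialization", {
  train <- train_pairs(1:6)
  cfg <- cnn_config(depth = 1, base_filters = 2, epochs = 1, batch_size = 3,
                    input_size = c(32, 32), seed = 4)
  m <- train_provider(train, train, cfg)
  path <- file.path(withr::local_tempdir(), "provider.rds")
  save_provider(m, path)
  m2 <- load_provider(path)
  p1 <- predict_provider(m, train[[1]]$image)
  p2 <- predict_provider(m2, train[[1]]$image)
  expect_identical(p1$p_kidney, p2$p_kidney)
  csv <- file.path(withr::local_tempdir(), "curves.csv")
  write_curves(m, csv)
  expect_true(all(c("epoch", "train_loss", "val_loss", "train_acc", "val_acc") %in%
                    names(utils::read.csv(csv))))
})
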