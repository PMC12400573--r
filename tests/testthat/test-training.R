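test_that("loss components match their closed forms", {
  p <- matrix(runif(100), 10, 10)
  expect_equal(dice_loss(p, p), 0, tolerance = 1e-12)
  expect_equal(rmse_loss(p, p), 0)
  expect_equal(total_loss(p, p), 0, tolerance = 1e-12)
  # all-zero prediction vs a single hot pixel
  t1 <- matrix(0, 10, 10); t1[3, 3] <- 1
  z <- matrix(0, 10, 10)
  eps <- 1e-5
  expect_equal(dice_loss(z, t1), 1 - eps / (1 + eps), tolerance = 1e-12)
  expect_equal(rmse_loss(z, t1), sqrt(1 / 100))
  expect_equal(total_loss(z, t1),
               0.6 * (1 - eps / (1 + eps)) + 0.4 * 0.1, tolerance = 1e-4)
  # degenerate both-zero maps
  expect_equal(dice_loss(z, z), 0)
  # constant offset: RMSE equals |d|
  expect_equal(rmse_loss(p, p + 0.25), 0.25, tolerance = 1e-12)
  # weighted composition with explicit components
  cfg <- loss_config()
  expect_equal(0.6 * 0.5 + 0.4 * 0.25, 0.4)
  expect_error(dice_loss(p, matrix(0, 5, 5)), "shape")
})

test_that("dice loss is invariant to joint spatial permutation", {
  set.seed(9)
  p <- matrix(runif(64), 8, 8)
  t <- matrix(runif(64), 8, 8)
  perm <- sample(64)
  expect_equal(dice_loss(p, t),
               dice_loss(matrix(p[perm], 8, 8), matrix(t[perm], 8, 8)))
})

test_that("total loss is non-negative and vanishes only at equality", {
  set.seed(10)
  for (i in 1:20) {
    p <- matrix(runif(36), 6, 6)
    t <- matrix(runif(36), 6, 6)
    l <- total_loss(p, t)
    expect_gte(l, 0)
    if (max(abs(p - t)) > 1e-3) expect_gt(l, 0)
  }
})

test_that("the optimizer makes real progress on a learnable pair", {
  pair <- sim_pairs(1, 70, shape = c(64L, 64L), n_spots = 12L)
  model <- build_enhancement_net(tiny_net_config(), seed = 5)
  model <- train_model(model, pair, pair,
                       cfg = train_config(epochs = 50, batch_size = 1,
                                          learning_rate = 1e-3, seed = 2,
                                          augment = FALSE))
  h <- attr(model, "history")
  expect_lt(h$train_loss[nrow(h)], 0.5 * h$train_loss[1])
  # beats the all-zeros predictor on validation
  tgt <- make_target(pair[[1]]$spots, c(64, 64), target_config())
  zeros_loss <- total_loss(matrix(0, 64, 64), tgt$data)
  expect_lt(min(h$val_loss), zeros_loss)
})

test_that("checkpointing keeps snapshots and the best-validation weights", {
  td <- withr::local_tempdir()
  pairs <- sim_pairs(3, 80, shape = c(64L, 64L))
  model <- build_enhancement_net(tiny_net_config(), seed = 6)
  model <- train_model(model, pairs[1:2], pairs[3],
                       cfg = train_config(epochs = 12, batch_size = 2,
                                          snapshot_every = 5, seed = 3),
                       checkpoint_dir = td)
  expect_true(file.exists(file.path(td, "epoch_5.ckpt")))
  expect_true(file.exists(file.path(td, "epoch_10.ckpt")))
  expect_false(file.exists(file.path(td, "epoch_12.ckpt")))
  expect_true(file.exists(file.path(td, "best.ckpt")))
  h <- attr(model, "history")
  expect_equal(attr(model, "best_epoch"), which.min(h$val_loss))
  best <- load_checkpoint(file.path(td, "best.ckpt"))
  expect_equal(best$extra$epoch, which.min(h$val_loss))
  hist <- jsonlite::fromJSON(file.path(td, "history.json"))
  expect_equal(hist$best_epoch, which.min(h$val_loss))
  expect_equal(length(hist$epochs$val_loss), 12)
})

test_that("training is reproducible under a fixed seed", {
  pairs <- sim_pairs(2, 200, shape = c(64L, 64L))
  run <- function() {
    m <- build_enhancement_net(tiny_net_config(), seed = 11)
    m <- train_model(m, pairs[1], pairs[2],
                     cfg = train_config(epochs = 3, batch_size = 1, seed = 11))
    attr(m, "history")
  }
  expect_equal(run(), run())
})

test_that("degenerate training inputs are rejected", {
  pairs <- sim_pairs(1, 300, shape = c(64L, 64L))
  model <- build_enhancement_net(tiny_net_config(), seed = 1)
  expect_error(train_model(model, list(), pairs), "non-empty")
  expect_error(train_model(model, pairs, list()), "non-empty")
})
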