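test_that("the default architecture lands on the published parameter budget", {
  model <- build_enhancement_net(seed = 1)
  expect_equal(count_parameters(model), 162761L)
  expect_equal(round(count_parameters(model) / 1000), 163)
  # stem alone: (9*1*32 + 32) + (9*32*32 + 32)
  stem <- grep("^stem\\.", names(model$params), value = TRUE)
  expect_equal(sum(vapply(model$params[stem], length, 0L)), 9568L)
  # doubling the width roughly quadruples the convolutional budget
  wide <- build_enhancement_net(network_config(base_channels = 64L), seed = 1)
  ratio <- count_parameters(wide) / count_parameters(model)
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 4.2)
  # monotone in width
  narrow <- build_enhancement_net(network_config(base_channels = 8L), seed = 1)
  expect_lt(count_parameters(narrow), count_parameters(model))
  # analytic cross-check of the full budget from the layer inventory
  C <- 32; hidden <- max(C %/% 16, 1)
  conv <- function(k, cin, cout) k * k * cin * cout + cout
  res_block <- conv(1, C, C) + 2 * C + conv(3, C, C) + 2 * C
  attention <- (C * hidden + hidden) + (hidden * C + C) + 7 * 7 * 2
  analytic <- conv(3, 1, C) + conv(3, C, C) +            # stem
    2 * (conv(3, C, C) + res_block) +                    # encoder levels
    res_block + attention + res_block +                  # bottleneck
    2 * (conv(3, C, C) + conv(3, 2 * C, C) + conv(3, C, C)) +  # decoder
    attention + conv(3, C, C) + conv(3, C, C) + conv(1, C, 1)  # head
  expect_equal(count_parameters(model), analytic)
})

test_that("the model preserves shape and stays in [0, 1] on awkward sizes", {
  model <- build_enhancement_net(seed = 2)
  for (d in list(c(100, 100), c(16, 48), c(37, 61))) {
    out <- apply_model(model, matrix(runif(prod(d)), d[1], d[2]))
    expect_equal(dim(out), d)
    expect_true(all(out >= 0 & out <= 1))
  }
  expect_error(apply_model(model, array(0, c(4, 8, 8))), "2D")
})

test_that("inference is deterministic and ImageND-aware", {
  model <- build_enhancement_net(seed = 3)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_identical(apply_model(model, x), apply_model(model, x))
  wrapped <- apply_model(model, image_nd(x))
  expect_s3_class(wrapped, "ImageND")
  expect_identical(wrapped$data, apply_model(model, x))
})

test_that("checkpoints roundtrip weights, config and BN state", {
  td <- withr::local_tempdir()
  model <- build_enhancement_net(tiny_net_config(), seed = 4)
  # a couple of training steps so BN running stats are non-trivial
  sim <- sim_pairs(2, 50, shape = c(64L, 64L))
  model <- train_model(model, sim[1], sim[2],
                       cfg = train_config(epochs = 2, batch_size = 1,
                                          seed = 1))
  f <- file.path(td, "m.ckpt")
  save_checkpoint(model, f, extra = list(note = "test"))
  back <- load_checkpoint(f)
  expect_equal(back$config, model$config)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_equal(apply_model(back, x), apply_model(model, x))
  expect_error(suppressWarnings(load_checkpoint(tempfile())), "")
})

test_that("the receptive field follows the architecture analytically", {
  expect_equal(receptive_field_radius(network_config()), 45L)
  # one fewer level: remove down conv (j=2 stage) contributions
  expect_lt(receptive_field_radius(network_config(n_levels = 1L)),
            receptive_field_radius(network_config()))
  expect_gt(receptive_field_radius(network_config(n_levels = 3L)),
            receptive_field_radius(network_config()))
})
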