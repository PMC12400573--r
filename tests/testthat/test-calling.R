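test_that("maxima mode agrees with a brute-force neighbourhood oracle", {
  set.seed(21)
  for (rep in 1:5) {
    m <- matrix(0, 24, 24)
    # a few random smooth bumps
    for (k in 1:4) {
      cy <- sample(4:19, 1); cx <- sample(4:19, 1)
      h <- runif(1, 0.5, 1)
      for (dy in -3:3) for (dx in -3:3) {
        m[cy + dy, cx + dx] <- max(m[cy + dy, cx + dx],
                                   h * exp(-(dy^2 + dx^2) / 4))
      }
    }
    oracle <- brute_maxima_2d(m, 0.5)
    called <- call_spots_maxima(image_nd(m), call_config(threshold = 0.5))
    expect_equal(nrow(called), NROW(oracle))
    if (NROW(oracle)) {
      o <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
      g <- as.matrix(called)[order(called$y, called$x), , drop = FALSE]
      expect_equal(unname(g), unname(o), tolerance = 1e-12)
    }
  }
})

test_that("maxima mode honours the threshold and empty images", {
  expect_equal(nrow(call_spots_maxima(image_nd(matrix(0, 16, 16)))), 0)
  m <- matrix(0, 16, 16)
  m[8, 8] <- 0.4
  expect_equal(nrow(call_spots_maxima(image_nd(m),
                                      call_config(threshold = 0.5))), 0)
  expect_equal(nrow(call_spots_maxima(image_nd(m),
                                      call_config(threshold = 0.3))), 1)
})

test_that("ideal gaussian targets are recovered exactly", {
  s <- spot_table(data.frame(y = c(5, 20), x = c(5, 30)))
  tgt <- make_gaussian_target(s, c(40, 40), sigma = 1)
  called <- call_spots_maxima(tgt)
  got <- as.matrix(called)[order(called$y), ]
  expect_equal(unname(got), matrix(c(5, 5, 20, 30), 2, byrow = TRUE))
})

test_that("plateaus yield one detection at the plateau centroid", {
  m <- matrix(0, 16, 16)
  m[6:8, 6:8] <- 0.9  # flat-top 3x3 plateau
  called <- call_spots_maxima(image_nd(m))
  expect_equal(nrow(called), 1)
  expect_equal(as.numeric(called[1, ]), c(6, 6))  # 0-based centroid of 6:8
})

test_that("raising the threshold never adds detections", {
  set.seed(23)
  m <- matrix(runif(32 * 32), 32, 32)
  m <- conv_sep_test(m)
  counts <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8), function(th) {
    nrow(call_spots_maxima(image_nd(m), call_config(threshold = th)))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})


test_that("components mode reports intensity-weighted centroids", {
  # one 13-px disk of uniform intensity: centroid at the disk centre
  s <- spot_table(data.frame(y = 6, x = 6))
  blob <- make_dilation_target(s, c(13, 13), radius = 2)
  called <- call_spots_components(blob, call_config())
  expect_equal(nrow(called), 1)
  expect_equal(as.numeric(called[1, ]), c(6, 6))
  # empty image
  expect_equal(nrow(call_spots_components(image_nd(matrix(0, 8, 8)))), 0)
})

test_that("watershed splits fused twin blobs into two centroids", {
  # two gaussian peaks 5 px apart fuse into one component above threshold
  s <- spot_table(data.frame(y = c(10, 10), x = c(8, 13)))
  tgt <- make_gaussian_target(s, c(21, 21), sigma = 1.6)
  mask <- tgt$data >= 0.5
  labs <- table(fishspotr:::label_components_cpp(as.vector(mask), dim(tgt$data)))
  expect_equal(length(labs) - 1, 1)  # single fused component (plus bg)
  expect_gt(sum(mask), 13)
  called <- call_spots_components(tgt, call_config(threshold = 0.5))
  expect_equal(nrow(called), 2)
  m <- match_spots(called, s, match_config(cutoff = 1))
  expect_equal(m$tp, 2)
  expect_true(all(m$pairs$distance < 1))
})

test_that("3D maxima calling works with 26-connectivity", {
  a <- array(0, c(12, 12, 12))
  a[4, 4, 4] <- 0.9
  a[9, 9, 9] <- 0.8
  called <- call_spots_maxima(image_nd(a, c("z", "y", "x")))
  expect_equal(nrow(called), 2)
  expect_equal(names(called), c("z", "y", "x"))
  got <- as.matrix(called)[order(called$z), ]
  expect_equal(unname(got), matrix(c(3, 3, 3, 8, 8, 8), 2, byrow = TRUE))
})
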