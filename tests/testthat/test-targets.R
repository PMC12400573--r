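test_that("single-pixel targets stamp exactly one hot pixel per distinct spot", {
  s <- spot_table(data.frame(y = 5, x = 5))
  tgt <- make_single_pixel_target(s, c(11, 11))
  expect_equal(sum(tgt$data != 0), 1)
  expect_equal(tgt$data[6, 6], 1)
  # empty table
  expect_true(all(make_single_pixel_target(spot_table(), c(8, 8))$data == 0))
  # duplicates collapse
  dup <- spot_table(data.frame(y = c(5, 5), x = c(5, 5)))
  expect_equal(make_single_pixel_target(dup, c(11, 11))$data, tgt$data)
  # subpixel coordinates round half away from zero
  sub <- spot_table(data.frame(y = 2.5, x = 3.49))
  t2 <- make_single_pixel_target(sub, c(8, 8))
  expect_equal(which(t2$data == 1, arr.ind = TRUE)[1, ], c(row = 4, col = 4))
  # out-of-bounds spots name the offending row
  oob <- spot_table(data.frame(y = c(1, 20), x = c(1, 1)))
  expect_error(make_single_pixel_target(oob, c(11, 11)), "row 2")
})

test_that("dilation targets cover the Euclidean disk", {
  # independent oracle: enumerate integer offsets with ||d|| <= r
  n_offsets <- function(r) sum(outer((-r):r, (-r):r,
                                     function(a, b) a^2 + b^2) <= r^2)
  expect_equal(n_offsets(2), 13)
  s <- spot_table(data.frame(y = 5, x = 5))
  tgt <- make_dilation_target(s, c(11, 11), radius = 2)
  expect_equal(sum(tgt$data), 13)
  # corner spot: only in-bounds offsets survive (quadrant of the disk)
  corner <- make_dilation_target(spot_table(data.frame(y = 0, x = 0)),
                                 c(11, 11), radius = 2)
  g <- expand.grid(dy = 0:2, dx = 0:2)
  expect_equal(sum(corner$data), sum(g$dy^2 + g$dx^2 <= 4))
  expect_true(all(make_dilation_target(spot_table(), c(8, 8))$data == 0))
})

test_that("gaussian targets have unit peaks with the sampled-kernel profile", {
  s <- spot_table(data.frame(y = 5, x = 5))
  tgt <- make_gaussian_target(s, c(11, 11), sigma = 1)
  expect_equal(tgt$data[6, 6], 1)
  expect_equal(tgt$data[6, 7] / tgt$data[6, 6], exp(-0.5), tolerance = 1e-9)
  # empty table: zeros, no division by zero
  expect_true(all(make_gaussian_target(spot_table(), c(8, 8))$data == 0))
  # well-separated spots each reach ~1
  two <- spot_table(data.frame(y = c(10, 10), x = c(10, 30)))
  t2 <- make_gaussian_target(two, c(40, 40), sigma = 1)
  expect_equal(t2$data[11, 11], 1, tolerance = 1e-6)
  expect_equal(t2$data[11, 31], 1, tolerance = 1e-6)
  expect_true(all(t2$data >= 0 & t2$data <= 1))
})

test_that("gaussian-target maxima sit exactly on the stamped pixels", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 8
    coords <- place_well_separated(n, c(64, 64), 6 * 1.0 + 2)
    s <- spot_table(data.frame(y = coords[, 1], x = coords[, 2]))
    tgt <- make_gaussian_target(s, c(64, 64), sigma = 1)
    called <- call_spots_maxima(tgt, call_config(threshold = 0.4))
    stamped <- spot_table(data.frame(y = floor(coords[, 1] + 0.5),
                                     x = floor(coords[, 2] + 0.5)))
    m <- match_spots(called, stamped, match_config(cutoff = 1))
    expect_equal(m$tp, n)
    expect_equal(max(m$pairs$distance), 0)
  }
})

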