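test_that("2D slice routing normalizes then applies the model per slice", {
  stub <- enhancer_identity()
  sim <- simulate_field(simulation_config(shape = c(64, 64), n_spots = 10,
                                          seed = 1))
  enh <- enhance_2d(stub, sim$image)
  expect_equal(enh$data, normalize_image(sim$image)$data)
  # channels are enhanced independently and never mixed
  a <- array(runif(3 * 32 * 32), c(3, 32, 32))
  img <- image_nd(a, c("c", "y", "x"))
  enh3 <- enhance_2d(stub, img)
  for (cc in 1:3) {
    expect_equal(enh3$data[cc, , ],
                 fishspotr:::normalize_slice(a[cc, , ], normalization_spec()))
  }
  expect_error(enhance_2d(stub, image_nd(matrix(0, 4, 4), c("z", "y"))), "")
})

test_that("enhance_2d commutes with leading-axis slicing", {
  model <- build_enhancement_net(tiny_net_config(), seed = 7)
  a <- array(runif(2 * 32 * 32), c(2, 32, 32))
  img <- image_nd(a, c("t", "y", "x"))
  whole <- enhance_2d(model, img)
  t0 <- enhance_2d(model, image_nd(a[1, , ], c("y", "x")))
  expect_equal(whole$data[1, , ], t0$data)
})

test_that("tri-axial blending is the elementwise product of three passes", {
  stub <- enhancer_identity()
  v <- array(runif(16 * 16 * 16), c(16, 16, 16))
  img <- image_nd(v, c("z", "y", "x"))
  # with normalization disabled the identity stub passes values through,
  # so the blend is exactly v^3
  blend <- enhance_3d_blend(stub, img, norm_spec = NULL)
  expect_equal(blend$data, v^3, tolerance = 1e-12)
  ones <- image_nd(array(1, c(16, 16, 16)), c("z", "y", "x"))
  expect_equal(enhance_3d_blend(stub, ones, norm_spec = NULL)$data,
               array(1, c(16, 16, 16)))
  # blended output never exceeds any single-axis stack
  blendn <- enhance_3d_blend(stub, img)
  zstack <- enhance_2d(stub, img)
  expect_true(all(blendn$data <= zstack$data + 1e-12))
  expect_error(enhance_3d_blend(stub, image_nd(array(0, c(8, 32, 32)),
                                               c("z", "y", "x"))),
               "spatial extent")
})

test_that("blending suppresses duplicate detections along z", {
  stub <- enhancer_matched_filter(1.3)
  fp_counts <- c(zonly = 0, blend = 0)
  for (s in 1:4) {
    sim <- simulate_volume(simulation_config(shape = c(32, 64, 64),
                                             n_spots = 15, psf_sigma = 1.3,
                                             min_separation = 8, seed = s))
    cc <- call_config(threshold = 0.3)
    count_fp <- function(enh) {
      match_spots(call_spots_maxima(enh, cc), sim$spots)$fp
    }
    fp_counts["zonly"] <- fp_counts["zonly"] + count_fp(enhance_2d(stub, sim$image))
    fp_counts["blend"] <- fp_counts["blend"] + count_fp(enhance_3d_blend(stub, sim$image))
  }
  expect_lt(fp_counts["blend"], fp_counts["zonly"])
})

test_that("chunked enhancement equals monolithic for the network model", {
  sim <- simulate_field(simulation_config(shape = c(256, 256), n_spots = 40,
                                          seed = 13))
  model <- build_enhancement_net(seed = 8)
  mono <- enhance_2d(model, sim$image)
  chk <- enhance_chunked(model, sim$image,
                         plan = chunk_plan(c(y = 96L, x = 96L)))
  expect_lt(max(abs(chk$data - mono$data)), 1e-5)
  # zero halo: interiors still match at a receptive field from block edges
  chk0 <- enhance_chunked(model, sim$image,
                          plan = chunk_plan(c(y = 96L, x = 96L), halo = 0))
  rf <- receptive_field_radius(model$config)
  ok <- matrix(FALSE, 256, 256)
  for (b0 in seq(0, 255, 96)) {
    lo <- b0 + rf + 1
    hi <- min(b0 + 96, 256) - rf
    if (lo <= hi) ok[lo:hi, ] <- TRUE
  }
  ok2 <- matrix(FALSE, 256, 256)
  for (b0 in seq(0, 255, 96)) {
    lo <- b0 + rf + 1
    hi <- min(b0 + 96, 256) - rf
    if (lo <= hi) ok2[, lo:hi] <- TRUE
  }
  sel <- ok & ok2
  expect_gt(sum(sel), 0)
  expect_lt(max(abs(chk0$data[sel] - mono$data[sel])), 1e-5)
})

test_that("chunked zarr output carries the requested chunk grid", {
  td <- withr::local_tempdir()
  sim <- simulate_field(simulation_config(shape = c(96, 96), n_spots = 10,
                                          seed = 17))
  src <- file.path(td, "in.zarr")
  write_image(sim$image, src, chunks = c(32L, 32L))
  dst <- file.path(td, "out.zarr")
  stub <- enhancer_matched_filter(1.3)
  enhance_chunked(stub, src, dst, plan = chunk_plan(c(y = 48L, x = 48L)))
  st <- zarr_open(dst)
  expect_equal(st$chunks, c(48L, 48L))
  expect_equal(st$shape, c(96L, 96L))
  out <- read_image(dst)
  expect_true(all(out$data >= 0 & out$data <= 1))
})

test_that("chunked 3d blending matches the in-memory path", {
  td <- withr::local_tempdir()
  sim <- simulate_volume(simulation_config(shape = c(16, 32, 32), n_spots = 6,
                                           seed = 19))
  stub <- enhancer_matched_filter(1.3)
  mono <- enhance_3d_blend(stub, sim$image)
  src <- file.path(td, "v.zarr")
  write_image(sim$image, src, chunks = c(4L, 16L, 16L))
  dst <- file.path(td, "vb.zarr")
  enhance_chunked(stub, src, dst, mode = "3d_blend")
  expect_equal(read_image(dst)$data, mono$data, tolerance = 1e-10)
})
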