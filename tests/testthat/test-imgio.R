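test_that("TIFF roundtrips preserve float and integer grids", {
  td <- withr::local_tempdir()
  # float image in [0,1]
  m <- matrix(runif(64 * 64), 64, 64)
  f <- file.path(td, "f.tif")
  write_image(image_nd(m), f)
  r <- read_image(f)
  expect_equal(r$axes, c("y", "x"))
  expect_lt(max(abs(r$data - m)), 1e-7)
  # photon-scale float image: float32 storage, relative precision
  mp <- matrix(runif(32 * 32) * 2000, 32, 32)
  write_image(image_nd(mp), f)
  expect_lt(max(abs(read_image(f)$data - mp)) / 2000, 1e-6)
  # uint16 image: bitwise
  mi <- matrix(sample(0:65535, 32 * 32, replace = TRUE), 32, 32)
  write_image(image_nd(mi), f)
  expect_identical(as.integer(read_image(f)$data), as.integer(mi))
  # 3D stack roundtrips page-wise with axes metadata
  a <- array(runif(4 * 16 * 16), c(4, 16, 16))
  write_image(image_nd(a, c("z", "y", "x")), f)
  r3 <- read_image(f)
  expect_equal(r3$axes, c("z", "y", "x"))
  expect_lt(max(abs(r3$data - a)), 1e-7)
})

test_that("zarr roundtrips, preserves axes metadata and chunk layout", {
  td <- withr::local_tempdir()
  a <- array(runif(3 * 20 * 24), c(3, 20, 24))
  p <- file.path(td, "img.zarr")
  write_image(image_nd(a, c("c", "y", "x")), p, chunks = c(1L, 8L, 8L))
  st <- zarr_open(p)
  expect_equal(st$chunks, c(1L, 8L, 8L))
  r <- read_image(p)
  expect_equal(r$axes, c("c", "y", "x"))
  expect_equal(r$data, a)
  # partial reads agree with in-memory slicing
  sub <- zarr_read_sub(st, c(1L, 5L, 3L), c(2L, 10L, 12L))
  expect_equal(sub, a[2:3, 6:15, 4:15, drop = FALSE])
  # read-modify-write across chunk borders
  patch <- array(-1, c(1L, 5L, 5L))
  zarr_write_sub(st, c(0L, 6L, 6L), patch)
  a[1, 7:11, 7:11] <- -1
  expect_equal(zarr_read_full(st), a)
})

test_that("N5 and NPZ roundtrip with full fidelity", {
  td <- withr::local_tempdir()
  a <- array(rnorm(5 * 12 * 18), c(5, 12, 18))
  pn <- file.path(td, "img.n5")
  write_image(image_nd(a, c("z", "y", "x")), pn)
  rn <- read_image(pn)
  expect_equal(rn$data, a)
  expect_equal(rn$axes, c("z", "y", "x"))
  pz <- file.path(td, "img.npz")
  write_image(image_nd(a, c("z", "y", "x")), pz)
  expect_equal(read_image(pz)$data, a)
  # 4D containers work where TIFF cannot
  a4 <- array(runif(2 * 3 * 8 * 8), c(2, 3, 8, 8))
  expect_error(write_image(image_nd(a4), file.path(td, "x.tif")), "rank")
  p4 <- file.path(td, "img4.zarr")
  write_image(image_nd(a4), p4)
  expect_equal(read_image(p4)$data, a4)
})

test_that("python's numpy/zarr read our NPY and zarr output", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  td <- withr::local_tempdir()
  a <- array(rnorm(4 * 6 * 8), c(4, 6, 8))
  pz <- file.path(td, "img.npz")
  write_image(image_nd(a, c("z", "y", "x")), pz)
  script <- sprintf(
    "import numpy as np; d = np.load('%s'); a = d['image']; print(a.shape); print(round(float(a[1,2,3]), 9))",
    pz)
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  expect_equal(out[1], "(4, 6, 8)")
  expect_equal(as.numeric(out[2]), a[2, 3, 4], tolerance = 1e-8)
})

test_that("image rank limits and unknown formats are rejected", {
  a6 <- array(0, rep(2, 6))
  expect_error(image_nd(a6), "rank")
  expect_error(read_image("x.dat", format = "weird"), "format")
  td <- withr::local_tempdir()
  expect_error(write_image(image_nd(matrix(0, 16, 16)),
                           file.path(td, "missing_dir", "x.tif")),
               "parent directory")
})

test_that("spot table CSV dialects roundtrip", {
  td <- withr::local_tempdir()
  f <- file.path(td, "s.csv")
  writeLines("y,x\n5,5\n20,30", f)
  s <- read_spot_table(f)
  expect_equal(nrow(s), 2)
  expect_equal(names(s), c("y", "x"))
  expect_equal(s$x, c(5, 30))
  # positional dialect maps onto trailing spatial axes
  writeLines("axis-0,axis-1,axis-2\n1,2,3", f)
  s3 <- read_spot_table(f)
  expect_equal(names(s3), c("z", "y", "x"))
  expect_equal(as.numeric(s3[1, ]), c(1, 2, 3))
  # write -> read preserves subpixel coordinates
  orig <- spot_table(data.frame(y = c(1.123456, 60.5), x = c(2.654321, 3)))
  write_spot_table(orig, f)
  back <- read_spot_table(f)
  expect_equal(as.matrix(back), as.matrix(orig), tolerance = 1e-6)
  # non-numeric cells are reported with their row
  writeLines("y,x\n1,2\nfoo,4", f)
  expect_error(read_spot_table(f), "row 2")
})

test_that("percentile normalization matches its closed form and is idempotent", {
  # constant image maps to zeros
  expect_true(all(normalize_image(image_nd(matrix(7, 16, 16)))$data == 0))
  # 0..1000 with defaults: full [0, 1] output range
  m <- matrix(rep(0:1000, length.out = 32 * 32), 32, 32)
  nm <- normalize_image(image_nd(m))$data
  expect_equal(max(nm), 1)
  expect_equal(min(nm), 0)
  # linear ramp: output equals the analytic clipped affine map
  v <- seq(0, 1, length.out = 1024)
  r <- matrix(v, 32, 32)
  spec <- normalization_spec(1, 99.9)
  qs <- quantile(v, c(0.01, 0.999), names = FALSE, type = 1)
  expected <- pmin(pmax((r - qs[1]) / (qs[2] - qs[1]), 0), 1)
  expect_equal(normalize_image(image_nd(r), spec)$data, expected)
  # idempotence
  once <- normalize_image(image_nd(r), spec)
  twice <- normalize_image(once, spec)
  expect_lt(max(abs(twice$data - once$data)), 1e-6)
  # slices are normalized independently
  a <- array(0, c(2, 16, 16))
  a[1, , ] <- matrix(runif(256), 16)
  a[2, , ] <- matrix(runif(256) * 100, 16)
  na <- normalize_image(image_nd(a, c("c", "y", "x")))$data
  expect_equal(max(na[1, , ]), 1)
  expect_equal(max(na[2, , ]), 1)
})

test_that("axis bookkeeping enforces the canonical order", {
  expect_error(image_nd(array(0, c(4, 4, 4)), c("y", "x", "z")), "order")
  expect_error(image_nd(matrix(0, 4, 4), c("y", "y")), "unique")
  img <- image_nd(array(0, c(2, 3, 4, 5)), c("c", "z", "y", "x"))
  expect_equal(img$axes, c("c", "z", "y", "x"))
  expect_error(image_nd(matrix(c(0, NA), 4, 4)), "finite")
})
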