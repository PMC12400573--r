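test_that("simulation is seed-deterministic and respects its contract", {
  cfg <- simulation_config(shape = c(64, 64), n_spots = 50, seed = 7)
  a <- simulate_field(cfg)
  b <- simulate_field(cfg)
  expect_identical(a$image$data, b$image$data)
  expect_identical(as.matrix(a$spots), as.matrix(b$spots))
  expect_equal(nrow(a$spots), 50)
  expect_true(validate_spots_in_bounds(a$spots, a$image))
})

test_that("an empty field is pure background", {
  cfg <- simulation_config(shape = c(64, 64), n_spots = 0,
                           background_level = 100,
                           gaussian_read_noise_sd = 5, seed = 1)
  sim <- simulate_field(cfg)
  expect_equal(nrow(sim$spots), 0)
  # mean ~ Poisson(100) + N(0, 5); SE of the mean over 4096 px
  se <- sqrt((100 + 25) / length(sim$image$data))
  expect_lt(abs(mean(sim$image$data) - 100), 3 * se)
})

test_that("noiseless rendering conserves photons", {
  # seed chosen so every spot sits well inside the field: border clipping
  # would otherwise dominate the truncation tolerance
  cfg <- simulation_config(shape = c(96, 96), n_spots = 6, psf_sigma = 1.3,
                           background_level = 50, seed = 3,
                           min_separation = 12)
  sim <- simulate_field(cfg)
  ctr <- as.matrix(sim$spots)
  expect_true(all(ctr > 8 & ctr < 87))
  total <- sum(sim$noiseless$data)
  expected <- 50 * 96^2 + sum(sim$amplitudes) * 2 * pi * 1.3^2
  expect_lt(abs(total - expected) / expected, 0.01)
})

test_that("spot calling on the noiseless image recovers every centre", {
  cfg <- simulation_config(shape = c(96, 96), n_spots = 10, psf_sigma = 1.3,
                           background_level = 0, gaussian_read_noise_sd = 0,
                           min_separation = 12, seed = 3)
  sim <- simulate_field(cfg)
  enh <- image_nd(sim$noiseless$data / max(sim$noiseless$data))
  called <- call_spots_components(enh, call_config(threshold = 0.02,
                                                   size_split_threshold = 200L))
  m <- match_spots(called, sim$spots, match_config(cutoff = 0.5))
  expect_equal(m$tp, 10)
  expect_lt(max(m$pairs$distance), 0.5)
})

test_that("3D volumes have the stated axial elongation", {
  cfg <- simulation_config(shape = c(32, 64, 64), n_spots = 10, seed = 5)
  sim <- simulate_volume(cfg)
  expect_equal(nrow(sim$spots), 10)
  expect_equal(names(sim$spots), c("z", "y", "x"))
  # noiseless single centred spot: z profile twice as wide as y profile
  one <- simulate_volume(simulation_config(
    shape = c(33, 65, 65), n_spots = 1, psf_sigma = 1.5,
    background_level = 0, gaussian_read_noise_sd = 0, seed = 8))
  vol <- one$noiseless$data
  pk <- which(vol == max(vol), arr.ind = TRUE)[1, ]
  fwhm <- function(profile) {
    half <- max(profile) / 2
    2 * sum(profile >= half) / 2  # crude integer FWHM
  }
  fz <- fwhm(vol[, pk[2], pk[3]])
  fy <- fwhm(vol[pk[1], , pk[3]])
  expect_gt(fz / fy, 1.5)
  expect_lt(fz / fy, 2.6)
  # argmax sits at the (rounded) true centre
  expect_lt(sqrt(sum((pk - 1 - as.numeric(one$spots[1, ]))^2)), 1)
})

test_that("infeasible min_separation raises a placement error", {
  cfg <- simulation_config(shape = c(16, 16), n_spots = 40,
                           min_separation = 10, seed = 1)
  expect_error(simulate_field(cfg), "could not place")
})

test_that("snr behaves like a signal-to-noise ratio", {
  # noiseless field with flat zero background hits the capped sentinel
  cfg0 <- simulation_config(shape = c(64, 64), n_spots = 5,
                            amplitude_range = c(100, 100),
                            background_level = 0, gaussian_read_noise_sd = 0,
                            min_separation = 15, seed = 2)
  sim0 <- simulate_field(cfg0)
  expect_equal(snr(sim0$noiseless, sim0$spots), 1e6)
  # pure noise with a fabricated spot list: SNR ~ 0
  set.seed(4)
  vals <- replicate(20, {
    img <- image_nd(matrix(rnorm(64 * 64, 100, 5), 64, 64))
    fake <- spot_table(data.frame(y = runif(5, 10, 50), x = runif(5, 10, 50)))
    snr(img, fake)
  })
  expect_lt(abs(mean(vals)), 4 * sd(vals) / sqrt(length(vals)))
  # doubling the amplitude doubles the SNR at fixed noise
  s1 <- simulate_field(simulation_config(shape = c(96, 96), n_spots = 8,
                                         amplitude_range = c(400, 400),
                                         min_separation = 14, seed = 9))
  s2 <- simulate_field(simulation_config(shape = c(96, 96), n_spots = 8,
                                         amplitude_range = c(800, 800),
                                         min_separation = 14, seed = 9))
  r1 <- snr(s1$image, s1$spots)
  r2 <- snr(s2$image, s2$spots)
  expect_lt(abs(r2 / r1 - 2), 0.2 * 2)
})
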