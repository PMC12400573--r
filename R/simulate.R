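#' Configuration for synthetic FISH fields
#'
#' Describes a diffraction-limited spot field: isotropic Gaussian
#' point-spread spots of varying amplitude on a flat background, sampled
#' with Poisson photon noise plus additive Gaussian read noise
#' (sCMOS/EMCCD-like statistics).
#'
#' @param shape per-axis extents, e.g. `c(y = 512, x = 512)` or a 3-vector
#'   for `(z, y, x)` volumes; every extent must be at least 16.
#' @param n_spots number of spots, or a length-2 range to sample uniformly.
#' @param psf_sigma Gaussian PSF sigma in pixels; a single lateral value or
#'   a per-axis vector for 3D. For volumes a scalar sigma is expanded with
#'   an axial sigma of twice the lateral value, emulating the axial
#'   elongation of a widefield PSF.
#' @param amplitude_range `(low, high)` peak amplitudes in photons.
#' @param background_level flat background in photons.
#' @param gaussian_read_noise_sd read noise standard deviation in photons.
#' @param min_separation minimum pairwise spot distance in pixels (0 = no
#'   constraint); enforced by rejection sampling.
#' @param seed integer seed; identical seeds give bitwise-identical fields.
#' @return a `SimulationConfig` object.
#' @export
simulation_config <- function(shape = c(512L, 512L), n_spots = 50L,
                              psf_sigma = 1.3,
                              amplitude_range = c(200, 1000),
                              background_level = 100,
                              gaussian_read_noise_sd = 5,
                              min_separation = 0, seed = NULL) {
  shape <- as.integer(shape)
  if (any(shape < 16L)) stop("all shape extents must be >= 16", call. = FALSE)
  if (length(shape) < 2L || length(shape) > 3L) {
    stop("shape must have 2 (y,x) or 3 (z,y,x) extents", call. = FALSE)
  }
  if (any(n_spots < 0)) stop("n_spots must be >= 0", call. = FALSE)
  if (any(psf_sigma <= 0)) stop("psf_sigma must be > 0", call. = FALSE)
  if (length(amplitude_range) != 2 || amplitude_range[1] > amplitude_range[2]) {
    stop("amplitude_range must be (low, high) with low <= high", call. = FALSE)
  }
  structure(list(shape = shape, n_spots = n_spots, psf_sigma = psf_sigma,
                 amplitude_range = amplitude_range,
                 background_level = background_level,
                 gaussian_read_noise_sd = gaussian_read_noise_sd,
                 min_separation = min_separation, seed = seed),
            class = "SimulationConfig")
}

sim_axes <- function(config) {
  if (length(config$shape) == 2) c("y", "x") else c("z", "y", "x")
}

sim_sigmas <- function(config) {
  nd <- length(config$shape)
  s <- config$psf_sigma
  if (length(s) == nd) return(as.numeric(s))
  if (length(s) == 1) {
    if (nd == 2) return(rep(s, 2))
    return(c(2 * s, s, s))  # axial elongation: sigma_z = 2 x lateral
  }
  stop("psf_sigma must be scalar or one value per axis", call. = FALSE)
}

#' Simulate a synthetic FISH field
#'
#' Spot centres are placed uniformly at random (subject to
#' `min_separation`, by rejection), each rendered as
#' `amplitude * exp(-0.5 * sum(((r - r0) / sigma)^2))` sampled at pixel
#' centres and added to the flat background. The photon image is then
#' Poisson-sampled and Gaussian read noise is added. The returned table
#' holds the exact subpixel ground-truth centres.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `image` (an [image_nd()]) and `spots`
#'   (a [spot_table()]); `config$seed` fully determines the output.
#' @examples
#' sim <- simulate_field(simulation_config(shape = c(64, 64), n_spots = 5,
#'                                         seed = 1))
#' nrow(sim$spots)
#' @export
simulate_field <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  d <- config$shape
  nd <- length(d)
  axes <- sim_axes(config)
  sigma <- sim_sigmas(config)
  n <- if (length(config$n_spots) == 2) {
    sample(config$n_spots[1]:config$n_spots[2], 1)
  } else {
    as.integer(config$n_spots)
  }
  centers <- place_spots(n, d, config$min_separation)
  noiseless <- render_spots(d, centers, sigma, config$amplitude_range,
                            config$background_level)
  img <- noiseless$img
  img[] <- rpois(length(img), lambda = img)
  if (config$gaussian_read_noise_sd > 0) {
    img <- img + rnorm(length(img), sd = config$gaussian_read_noise_sd)
    img <- array(img, d)
  }
  spots <- spot_table(as.data.frame(setNames(
    lapply(seq_len(nd), function(i) centers[, i]), axes)))
  list(image = image_nd(img, axes), spots = spots,
       amplitudes = noiseless$amp, noiseless = image_nd(noiseless$img, axes))
}

#' Simulate a 3D volume of axially elongated spots
#'
#' Convenience wrapper around [simulate_field()] for `(z, y, x)` shapes; a
#' scalar `psf_sigma` is expanded to an anisotropic per-axis sigma with the
#' axial component doubled.
#'
#' @param config a [simulation_config()] with a 3-element shape.
#' @inherit simulate_field return
#' @export
simulate_volume <- function(config) {
  if (length(config$shape) != 3) {
    stop("simulate_volume needs a (z, y, x) shape", call. = FALSE)
  }
  simulate_field(config)
}

place_spots <- function(n, d, min_sep) {
  nd <- length(d)
  centers <- matrix(numeric(0), 0, nd)
  if (n == 0) return(centers)
  if (min_sep <= 0) {
    centers <- matrix(0, n, nd)
    for (i in seq_len(nd)) centers[, i] <- runif(n, 0, d[i] - 1)
    return(centers)
  }
  centers <- matrix(NA_real_, n, nd)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 1000L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(
        "could not place %d spots with min_separation %.2f after %d attempts",
        n, min_sep, max_attempts), call. = FALSE)
    }
    cand <- vapply(seq_len(nd), function(i) runif(1, 0, d[i] - 1), 0)
    if (placed > 0) {
      dd <- sweep(centers[seq_len(placed), , drop = FALSE], 2, cand)
      if (min(sqrt(rowSums(dd^2))) < min_sep) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  centers
}

render_spots <- function(d, centers, sigma, amplitude_range, background) {
  nd <- length(d)
  img <- array(background, d)
  n <- nrow(centers)
  amp <- if (n) runif(n, amplitude_range[1], amplitude_range[2]) else numeric(0)
  for (s in seq_len(n)) {
    ctr <- centers[s, ]
    lo <- pmax(0L, floor(ctr - 4 * sigma))
    hi <- pmin(d - 1L, ceiling(ctr + 4 * sigma))
    ax <- lapply(seq_len(nd), function(i) lo[i]:hi[i])
    gs <- lapply(seq_len(nd), function(i) {
      exp(-0.5 * ((ax[[i]] - ctr[i]) / sigma[i])^2)
    })
    patch <- Reduce(`%o%`, gs)
    idx <- lapply(ax, function(a) a + 1L)
    old <- do.call(`[`, c(list(img), idx, list(drop = FALSE)))
    img <- do.call(`[<-`, c(list(img), idx,
                            list(value = old + amp[s] * patch)))
  }
  list(img = img, amp = amp)
}

#' Signal-to-noise ratio of a spot field
#'
#' Defined as `(mean peak intensity at spot pixels - median background) /
#' (1.4826 * MAD of background)`, where background pixels lie farther than
#' `4 * psf_sigma` from every spot. When the background is exactly constant
#' (zero MAD), the capped sentinel `1e6` is returned.
#'
#' @param img an [image_nd()].
#' @param spots a [spot_table()] bound to `img`.
#' @param psf_sigma the PSF sigma used to delimit the background region.
#' @return a single number (capped at `1e6`).
#' @export
snr <- function(img, spots, psf_sigma = 1.3) {
  stopifnot(inherits(img, "ImageND"))
  if (!nrow(spots)) stop("snr needs at least one spot", call. = FALSE)
  d <- dim(img$data)
  nd <- length(d)
  sigma <- if (length(psf_sigma) == nd) psf_sigma else rep(max(psf_sigma), nd)
  centers <- as.matrix(as.data.frame(spots))
  near <- array(FALSE, d)
  r <- 4 * sigma
  for (s in seq_len(nrow(centers))) {
    ctr <- centers[s, ]
    lo <- pmax(0L, floor(ctr - r))
    hi <- pmin(d - 1L, ceiling(ctr + r))
    ax <- lapply(seq_len(nd), function(i) lo[i]:hi[i])
    ds <- lapply(seq_len(nd), function(i) ((ax[[i]] - ctr[i]) / r[i])^2)
    ball <- Reduce(function(a, b) outer(a, b, `+`), ds) <= 1
    idx <- lapply(ax, function(a) a + 1L)
    old <- do.call(`[`, c(list(near), idx, list(drop = FALSE)))
    near <- do.call(`[<-`, c(list(near), idx, list(value = old | ball)))
  }
  bg <- img$data[!near]
  if (!length(bg)) {
    stop("no background pixels farther than 4 sigma from all spots",
         call. = FALSE)
  }
  peak_idx <- round(centers) + 1
  peaks <- img$data[peak_idx[, seq_len(nd), drop = FALSE]]
  noise <- mad(bg)  # 1.4826 * MAD by default
  if (noise == 0) return(1e6)
  min((mean(peaks) - median(bg)) / noise, 1e6)
}
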