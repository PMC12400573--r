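#' Training target configuration
#'
#' Spot annotations are turned into target images in one of three modes:
#' a single hot pixel per spot, a morphological dilation of those pixels
#' with a Euclidean disk, or a Gaussian stamp normalized to peak 1. The
#' Gaussian mode is the recommended default: it gives the regression a
#' smooth, localized objective.
#'
#' @param mode `"single_pixel"`, `"dilation"` or `"gaussian"`.
#' @param sigma Gaussian stamp sigma in pixels (`gaussian` mode).
#' @param dilation_radius disk radius in pixels (`dilation` mode).
#' @return a `TargetConfig` object.
#' @export
target_config <- function(mode = c("gaussian", "single_pixel", "dilation"),
                          sigma = 1.0, dilation_radius = 2L) {
  mode <- match.arg(mode)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (dilation_radius < 1) stop("dilation_radius must be >= 1", call. = FALSE)
  structure(list(mode = mode, sigma = sigma,
                 dilation_radius = as.integer(dilation_radius)),
            class = "TargetConfig")
}

#' Render a target image from spot coordinates
#'
#' Dispatches on `config$mode`; see [make_single_pixel_target()],
#' [make_dilation_target()] and [make_gaussian_target()].
#'
#' @param spots a [spot_table()].
#' @param shape per-axis extents of the target image, in the spot table's
#'   axis order.
#' @param config a [target_config()].
#' @return an [image_nd()] with values in `[0, 1]`.
#' @export
make_target <- function(spots, shape, config = target_config()) {
  switch(config$mode,
    single_pixel = make_single_pixel_target(spots, shape),
    dilation = make_dilation_target(spots, shape, config$dilation_radius),
    gaussian = make_gaussian_target(spots, shape, config$sigma)
  )
}

# round half away from zero; annotations are stamped on integer pixels
round_half_up <- function(x) floor(x + 0.5)

stamp_indices <- function(spots, shape) {
  nd <- length(shape)
  if (ncol(spots) != nd) {
    stop("spot table dimensionality does not match target shape", call. = FALSE)
  }
  coords <- round_half_up(as.matrix(as.data.frame(spots)))
  for (j in seq_len(nd)) {
    bad <- which(coords[, j] < 0 | coords[, j] > shape[j] - 1)
    if (length(bad)) {
      stop(sprintf("spot row %d is out of bounds on axis '%s'",
                   bad[1], names(spots)[j]), call. = FALSE)
    }
  }
  coords
}

#' Single-pixel target
#'
#' Zeros everywhere except value 1 at each spot's nearest pixel; duplicate
#' rows collapse to a single hot pixel.
#'
#' @inheritParams make_target
#' @return an [image_nd()].
#' @export
make_single_pixel_target <- function(spots, shape) {
  shape <- as.integer(shape)
  tgt <- array(0, shape)
  if (nrow(spots)) {
    coords <- stamp_indices(spots, shape)
    tgt[coords + 1] <- 1
  }
  image_nd(tgt, spot_axes_or_default(spots, shape))
}

spot_axes_or_default <- function(spots, shape) {
  ax <- spot_axes(spots)
  if (length(ax) == length(shape) && all(ax %in% AXIS_ORDER)) ax else
    default_axes(length(shape))
}

#' Dilated-disk target
#'
#' The single-pixel target dilated with a Euclidean ball: every pixel whose
#' integer offset from a stamped pixel has norm at most `radius` is set
#' to 1. For radius 2 in 2D the disk covers 13 pixels.
#'
#' @inheritParams make_target
#' @param radius dilation radius in pixels.
#' @return an [image_nd()].
#' @export
make_dilation_target <- function(spots, shape, radius = 2L) {
  shape <- as.integer(shape)
  nd <- length(shape)
  tgt <- array(0, shape)
  if (nrow(spots)) {
    coords <- stamp_indices(spots, shape)
    offs <- disk_offsets(radius, nd)
    for (s in seq_len(nrow(coords))) {
      pts <- sweep(offs, 2, coords[s, ], `+`)
      keep <- rep(TRUE, nrow(pts))
      for (j in seq_len(nd)) {
        keep <- keep & pts[, j] >= 0 & pts[, j] <= shape[j] - 1
      }
      tgt[pts[keep, , drop = FALSE] + 1] <- 1
    }
  }
  image_nd(tgt, spot_axes_or_default(spots, shape))
}

disk_offsets <- function(radius, nd) {
  g <- expand.grid(rep(list(-radius:radius), nd))
  as.matrix(g[rowSums(g^2) <= radius^2, , drop = FALSE])
}

#' Gaussian-stamp target
#'
#' The single-pixel target convolved with a Gaussian kernel (truncated at
#' 4 sigma) and rescaled so the global maximum is 1; an empty table yields
#' an all-zero image.
#'
#' @inheritParams make_target
#' @param sigma kernel sigma in pixels.
#' @return an [image_nd()].
#' @export
make_gaussian_target <- function(spots, shape, sigma = 1.0) {
  shape <- as.integer(shape)
  nd <- length(shape)
  tgt <- array(0, shape)
  if (nrow(spots)) {
    coords <- unique(stamp_indices(spots, shape))
    r <- ceiling(4 * sigma)
    ker1 <- exp(-0.5 * ((-r):r / sigma)^2)
    for (s in seq_len(nrow(coords))) {
      ctr <- coords[s, ]
      lo <- pmax(0L, ctr - r)
      hi <- pmin(shape - 1L, ctr + r)
      ax <- lapply(seq_len(nd), function(i) lo[i]:hi[i])
      gs <- lapply(seq_len(nd), function(i) ker1[ax[[i]] - ctr[i] + r + 1])
      patch <- Reduce(`%o%`, gs)
      idx <- lapply(ax, function(a) a + 1L)
      old <- do.call(`[`, c(list(tgt), idx, list(drop = FALSE)))
      tgt <- do.call(`[<-`, c(list(tgt), idx, list(value = old + patch)))
    }
    mx <- max(tgt)
    if (mx > 0) tgt <- tgt / mx
  }
  image_nd(tgt, spot_axes_or_default(spots, shape))
}
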