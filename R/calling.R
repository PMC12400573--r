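#' Spot-calling configuration
#'
#' Detection on enhanced images uses fixed, dataset-independent rules: the
#' enhancement stage is what makes a single global threshold work across
#' sources.
#'
#' @param threshold intensity threshold in `(0, 1)` (default 0.5).
#' @param mode `"maxima"` (local maxima of the enhanced map, for models
#'   trained on single-pixel or Gaussian targets) or `"components"`
#'   (binarize, label, watershed-split oversized blobs; for dilation-target
#'   models).
#' @param size_split_threshold component size (pixels) above which a blob is
#'   split by watershed; defaults to the pixel count of the radius-2
#'   dilation disk (13).
#' @return a `CallConfig` object.
#' @export
call_config <- function(threshold = 0.5, mode = c("maxima", "components"),
                        size_split_threshold = 13L) {
  mode <- match.arg(mode)
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(threshold = threshold, mode = mode,
                 size_split_threshold = as.integer(size_split_threshold)),
            class = "CallConfig")
}

#' Call spots from an enhanced image
#'
#' Dispatches to [call_spots_maxima()] or [call_spots_components()] by
#' `config$mode`.
#'
#' @param enhanced a 2D or 3D [image_nd()] with values in `[0, 1]`.
#' @param config a [call_config()].
#' @return a [spot_table()].
#' @export
call_spots <- function(enhanced, config = call_config()) {
  if (config$mode == "maxima") call_spots_maxima(enhanced, config)
  else call_spots_components(enhanced, config)
}

#' Local-maxima spot calling
#'
#' Finds plateau-aware local maxima under full (8/26) connectivity: a
#' connected region of constant value strictly greater than all of its
#' neighbours counts once, located at the plateau centroid. Maxima whose
#' value falls below the threshold are discarded.
#'
#' @inheritParams call_spots
#' @return a [spot_table()] (possibly empty).
#' @export
call_spots_maxima <- function(enhanced, config = call_config()) {
  stopifnot(inherits(enhanced, "ImageND"))
  d <- dim(enhanced$data)
  if (length(d) > 3) {
    stop("spot calling expects a 2D or 3D image", call. = FALSE)
  }
  res <- local_maxima_cpp(as.vector(enhanced$data), as.integer(d),
                          config$threshold)
  coords_to_table(res[, seq_along(d), drop = FALSE], enhanced$axes)
}

# C++ reports coordinates in R dimension order (axis 1 first)
coords_to_table <- function(coords, axes) {
  df <- as.data.frame(coords)
  names(df) <- axes
  spot_table(df)
}

#' Connected-component spot calling with watershed splitting
#'
#' Binarizes the enhanced image at the threshold, labels connected
#' components (8-connectivity in 2D, 26 in 3D), and reports one
#' intensity-weighted centroid per component. Components larger than
#' `size_split_threshold` pixels are split by a watershed seeded from the
#' local maxima of the enhanced image inside the component, one centroid
#' per basin.
#'
#' @inheritParams call_spots
#' @return a [spot_table()].
#' @export
call_spots_components <- function(enhanced, config = call_config()) {
  stopifnot(inherits(enhanced, "ImageND"))
  d <- dim(enhanced$data)
  nd <- length(d)
  if (nd > 3) stop("spot calling expects a 2D or 3D image", call. = FALSE)
  x <- enhanced$data
  mask <- x >= config$threshold
  if (!any(mask)) return(spot_table(NULL, enhanced$axes))
  labels <- label_components_cpp(as.vector(mask), as.integer(d))
  sizes <- tabulate(labels[labels > 0])
  # seeds: all plateau maxima above threshold, mapped to their component
  mx <- local_maxima_cpp(as.vector(x), as.integer(d), config$threshold)
  seed_coords <- round(mx[, seq_len(nd), drop = FALSE])
  seed_lin <- lin_index(seed_coords, d)
  seed_comp <- labels[seed_lin]
  out <- vector("list", length(sizes))
  for (comp in seq_along(sizes)) {
    pix <- which(labels == comp)
    if (sizes[comp] <= config$size_split_threshold) {
      out[[comp]] <- weighted_centroid(pix, x, d)
      next
    }
    seeds <- seed_lin[seed_comp == comp]
    if (length(seeds) <= 1) {
      out[[comp]] <- weighted_centroid(pix, x, d)
      next
    }
    basins <- watershed_seeded_cpp(as.vector(x), as.vector(mask & labels == comp),
                                   as.integer(d), as.integer(seeds - 1L))
    cent <- lapply(seq_along(seeds), function(s) {
      weighted_centroid(which(basins == s), x, d)
    })
    out[[comp]] <- do.call(rbind, cent)
  }
  coords_to_table(do.call(rbind, out), enhanced$axes)
}

lin_index <- function(coords, d) {
  # coords: 0-based matrix in dimension order; returns 1-based linear index
  idx <- coords[, 1]
  mult <- 1
  for (j in seq_along(d)[-1]) {
    mult <- mult * d[j - 1]
    idx <- idx + coords[, j] * mult
  }
  as.integer(idx + 1)
}

weighted_centroid <- function(pix, x, d) {
  w <- x[pix]
  coords <- arrayInd(pix, d) - 1L
  matrix(colSums(coords * w) / sum(w), 1)
}
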