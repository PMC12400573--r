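#' @useDynLib fishspotr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile median mad rnorm runif rpois setNames
#' @importFrom utils unzip tail read.csv write.csv
NULL

AXIS_ORDER <- c("t", "c", "z", "y", "x")

#' n-dimensional microscopy image with named axes
#'
#' A dense intensity grid of rank 2 to 5 whose dimensions are labelled with a
#' contiguous-meaning subset of the canonical axis order `t, c, z, y, x`
#' (time, channel, axial, row, column). The first element of `dim(data)`
#' corresponds to the first axis label. Coordinates throughout the package
#' are 0-based and pixel-centred: the coordinate `(0, 0)` is the centre of
#' the first pixel, and integer coordinates fall on pixel centres.
#'
#' @param data numeric array (or matrix) of intensities; all values finite.
#' @param axes character vector of axis labels, one per dimension of `data`,
#'   drawn from `t, c, z, y, x` in that order. If `NULL`, axes are inferred
#'   from the rank: 2 = `(y, x)`, 3 = `(z, y, x)`, 4 = `(c, z, y, x)`,
#'   5 = `(t, c, z, y, x)`.
#' @param pixel_size optional named numeric vector of per-axis physical sizes
#'   in micrometres.
#' @return an object of class `ImageND` with elements `data`, `axes` and
#'   `pixel_size`.
#' @examples
#' img <- image_nd(matrix(runif(64 * 64), 64, 64))
#' img$axes
#' @export
image_nd <- function(data, axes = NULL, pixel_size = NULL) {
  if (is.null(dim(data))) stop("`data` must be a matrix or array", call. = FALSE)
  d <- dim(data)
  rank <- length(d)
  if (rank < 2L || rank > 5L) {
    stop(sprintf("unsupported image rank %d: must be between 2 and 5", rank),
         call. = FALSE)
  }
  if (is.null(axes)) axes <- default_axes(rank)
  axes <- as.character(axes)
  if (length(axes) != rank) {
    stop("`axes` length must equal the rank of `data`", call. = FALSE)
  }
  if (anyDuplicated(axes) || !all(axes %in% AXIS_ORDER)) {
    stop("`axes` must be unique labels drawn from t, c, z, y, x", call. = FALSE)
  }
  if (!identical(axes, AXIS_ORDER[AXIS_ORDER %in% axes])) {
    stop("`axes` must respect the canonical order t, c, z, y, x", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("image intensities must be finite", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, axes = axes, pixel_size = pixel_size),
            class = "ImageND")
}

default_axes <- function(rank) {
  switch(rank - 1L, c("y", "x"), c("z", "y", "x"),
         c("c", "z", "y", "x"), c("t", "c", "z", "y", "x"))
}

#' @export
print.ImageND <- function(x, ...) {
  cat(sprintf("<ImageND> %s  [%s]\n",
              paste(dim(x$data), collapse = " x "),
              paste(x$axes, collapse = ",")))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ImageND <- function(x) dim(x$data)

img_extent <- function(img, axis) dim(img$data)[match(axis, img$axes)]

#' Table of spot coordinates
#'
#' Point coordinates in pixel units, 0-based, with one numeric column per
#' axis. Integer coordinates lie on pixel centres; subpixel positions are
#' kept as floats.
#'
#' @param points a data frame or matrix of coordinates (may have 0 rows), or
#'   `NULL` for an empty table.
#' @param axes axis labels for the columns, matching the spatial axes of the
#'   associated image (for example `c("y", "x")` or `c("z", "y", "x")`).
#' @return an object of class `SpotTable` (a data frame).
#' @examples
#' spots <- spot_table(data.frame(y = c(5, 20), x = c(5, 30)))
#' @export
spot_table <- function(points = NULL, axes = NULL) {
  if (is.null(points)) {
    if (is.null(axes)) axes <- c("y", "x")
    points <- as.data.frame(setNames(rep(list(numeric(0)), length(axes)), axes))
  }
  points <- as.data.frame(points)
  if (is.null(axes)) {
    axes <- names(points)
  } else {
    if (length(axes) != ncol(points)) {
      stop("`axes` length must match the number of coordinate columns",
           call. = FALSE)
    }
    names(points) <- axes
  }
  if (!all(axes %in% AXIS_ORDER)) {
    stop("spot table axes must be drawn from t, c, z, y, x", call. = FALSE)
  }
  for (j in seq_along(points)) {
    points[[j]] <- as.numeric(points[[j]])
    if (anyNA(points[[j]])) {
      stop(sprintf("spot table column '%s' contains missing values", axes[j]),
           call. = FALSE)
    }
  }
  class(points) <- c("SpotTable", "data.frame")
  points
}

spot_axes <- function(spots) names(spots)

#' Check that all spots lie inside an image
#'
#' Every coordinate must lie in `[0, extent - 1]` of its axis.
#'
#' @param spots a [spot_table()].
#' @param img an [image_nd()] whose trailing axes match the spot columns, or
#'   an extent vector named by axis.
#' @return invisibly `TRUE`; errors naming the first offending row otherwise.
#' @export
validate_spots_in_bounds <- function(spots, img) {
  extents <- if (inherits(img, "ImageND")) {
    setNames(dim(img$data), img$axes)
  } else {
    img
  }
  for (ax in spot_axes(spots)) {
    if (!ax %in% names(extents)) {
      stop(sprintf("image has no '%s' axis to bind spots to", ax), call. = FALSE)
    }
    bad <- which(spots[[ax]] < 0 | spots[[ax]] > extents[[ax]] - 1)
    if (length(bad)) {
      stop(sprintf("spot row %d is out of bounds on axis '%s' (value %.3f, extent %d)",
                   bad[1], ax, spots[[ax]][bad[1]], extents[[ax]]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Robust percentile normalization spec
#'
#' @param low_percentile,high_percentile percentile bounds in `[0, 100]`,
#'   `low < high`. Defaults 1 and 99.9 resist hot pixels while using nearly
#'   the full dynamic range.
#' @return a `NormalizationSpec` object.
#' @export
normalization_spec <- function(low_percentile = 1.0, high_percentile = 99.9) {
  if (!(low_percentile >= 0 && low_percentile < high_percentile &&
        high_percentile <= 100)) {
    stop("need 0 <= low_percentile < high_percentile <= 100", call. = FALSE)
  }
  structure(list(low_percentile = low_percentile,
                 high_percentile = high_percentile),
            class = "NormalizationSpec")
}

#' Percentile-normalize an image slice-wise
#'
#' Each 2D `(y, x)` slice is independently rescaled to
#' `clip((x - P_low) / (P_high - P_low), 0, 1)` where `P_q` is the q-th
#' intensity percentile of that slice. A constant slice maps to all zeros.
#' Slice-wise scaling makes every plane presented to the enhancement model
#' occupy a comparable range regardless of per-plane illumination.
#'
#' @param img an [image_nd()].
#' @param spec a [normalization_spec()].
#' @return an [image_nd()] of the same shape with values in `[0, 1]`.
#' @export
normalize_image <- function(img, spec = normalization_spec()) {
  stopifnot(inherits(img, "ImageND"))
  out <- apply_yx_slices(img, function(m) normalize_slice(m, spec))
  out
}

normalize_slice <- function(m, spec) {
  if (is.null(spec)) return(m)  # input already normalized
  # type-1 (order statistic) percentiles make normalization exactly
  # idempotent: re-normalizing a clipped slice returns it unchanged
  qs <- quantile(m, c(spec$low_percentile, spec$high_percentile) / 100,
                 names = FALSE, type = 1)
  if (qs[2] <= qs[1]) return(array(0, dim(m)))
  pmin(pmax((m - qs[1]) / (qs[2] - qs[1]), 0), 1)
}

# apply f to every (y, x) slice across all leading indices; f maps matrix to
# matrix of identical shape
apply_yx_slices <- function(img, f) {
  ax <- img$axes
  iy <- match("y", ax); ix <- match("x", ax)
  if (is.na(iy) || is.na(ix)) stop("image lacks y or x axis", call. = FALSE)
  d <- dim(img$data)
  lead <- setdiff(seq_along(d), c(iy, ix))
  out <- img$data
  if (!length(lead)) {
    out[] <- f(img$data)
    return(image_nd(out, ax, img$pixel_size))
  }
  grid <- expand.grid(lapply(d[lead], seq_len))
  for (r in seq_len(nrow(grid))) {
    idx <- rep(list(quote(expr = )), length(d))
    for (k in seq_along(lead)) idx[[lead[k]]] <- grid[[k]][r]
    sl <- do.call(`[`, c(list(img$data), idx, list(drop = FALSE)))
    m <- matrix(sl, d[iy], d[ix])
    res <- f(m)
    out <- do.call(`[<-`, c(list(out), idx, list(value = array(res, dim(sl)))))
  }
  image_nd(out, ax, img$pixel_size)
}
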