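#' Read a microscopy image
#'
#' Supported containers: TIFF (2D, or multi-page 3D), Zarr v2 directory
#' stores, N5 datasets, and NPZ containers holding the key `"image"`. Axis
#' labels are taken from container metadata where present (Zarr/N5
#' attributes, TIFF description), otherwise inferred from the rank using the
#' canonical `t, c, z, y, x` convention.
#'
#' @param path file or directory path.
#' @param format `"tiff"`, `"zarr"`, `"n5"`, `"npz"` or `"auto"` (by
#'   extension / directory content).
#' @return an [image_nd()].
#' @export
read_image <- function(path, format = "auto") {
  format <- detect_format(path, format)
  switch(format,
    tiff = read_image_tiff(path),
    zarr = read_image_zarr(path),
    n5 = read_image_n5(path),
    npz = read_image_npz(path),
    stop(sprintf("unknown image format '%s'", format), call. = FALSE)
  )
}

detect_format <- function(path, format = "auto") {
  if (format != "auto") {
    if (!format %in% c("tiff", "zarr", "n5", "npz")) {
      stop(sprintf("unknown image format '%s'", format), call. = FALSE)
    }
    return(format)
  }
  lower <- tolower(path)
  if (grepl("\\.(tif|tiff)$", lower)) return("tiff")
  if (grepl("\\.npz$", lower)) return("npz")
  if (grepl("\\.zarr/?$", lower) || is_zarr_path(path)) return("zarr")
  if (grepl("\\.n5/?$", lower) || is_n5_path(path)) return("n5")
  stop(sprintf("cannot infer image format of '%s'", path), call. = FALSE)
}

read_image_tiff <- function(path) {
  # as.is=TRUE keeps integer samples verbatim but is rejected for float
  # pages; float samples are returned unscaled either way
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
    error = function(e) tiff::readTIFF(path, all = TRUE, info = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  axes <- NULL
  desc <- attr(pages[[1]], "description")
  if (!is.null(desc) && nzchar(desc) && grepl("axes", desc)) {
    meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
    if (!is.null(meta$axes)) axes <- strsplit(meta$axes, "")[[1]]
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p[, , 1] else p  # collapse grayscale-as-RGB
  })
  if (length(pages) == 1) {
    img <- image_nd(pages[[1]], axes %||% c("y", "x"))
  } else {
    d <- dim(pages[[1]])
    arr <- array(0, c(length(pages), d))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
    img <- image_nd(arr, axes %||% c("z", "y", "x"))
  }
  img
}

read_image_zarr <- function(path) {
  store <- zarr_open(path)
  if (length(store$shape) > 5) {
    stop(sprintf("unsupported image rank %d: must be between 2 and 5",
                 length(store$shape)), call. = FALSE)
  }
  axes <- NULL
  if (!is.null(store$attrs$axes)) axes <- strsplit(store$attrs$axes, "")[[1]]
  image_nd(zarr_read_full(store), axes)
}

read_image_n5 <- function(path) {
  res <- n5_read_array(path)
  if (length(dim(res$data)) > 5) {
    stop("unsupported image rank: must be between 2 and 5", call. = FALSE)
  }
  image_nd(res$data, res$axes)
}

read_image_npz <- function(path) {
  arr <- npz_read(path, key = "image")
  if (length(dim(arr)) > 5) {
    stop("unsupported image rank: must be between 2 and 5", call. = FALSE)
  }
  image_nd(arr)
}

#' Write a microscopy image
#'
#' Inverse of [read_image()]: `read_image(write_image(img, f), f)` restores
#' the grid bitwise for integer-valued data and to float32 precision for
#' real-valued data. TIFF output stores 2D images as one page and 3D images
#' as one page per leading-axis plane; higher ranks require Zarr, N5 or NPZ.
#'
#' @param img an [image_nd()].
#' @param path destination path.
#' @param format `"tiff"`, `"zarr"`, `"n5"`, `"npz"` or `"auto"`.
#' @param chunks optional chunk extents for Zarr output (defaults to the
#'   image shape, capped at 256 per axis).
#' @return invisibly, `path`.
#' @export
write_image <- function(img, path, format = "auto", chunks = NULL) {
  stopifnot(inherits(img, "ImageND"))
  format <- detect_format_write(path, format)
  parent <- dirname(path)
  if (!dir.exists(parent)) {
    stop(sprintf("parent directory '%s' does not exist", parent), call. = FALSE)
  }
  switch(format,
    tiff = write_image_tiff(img, path),
    zarr = write_image_zarr(img, path, chunks),
    n5 = write_image_n5(img, path),
    npz = npz_write(path, list(image = img$data))
  )
  invisible(path)
}

detect_format_write <- function(path, format) {
  if (format != "auto") {
    if (!format %in% c("tiff", "zarr", "n5", "npz")) {
      stop(sprintf("unknown image format '%s'", format), call. = FALSE)
    }
    return(format)
  }
  lower <- tolower(path)
  if (grepl("\\.(tif|tiff)$", lower)) return("tiff")
  if (grepl("\\.npz$", lower)) return("npz")
  if (grepl("\\.zarr/?$", lower)) return("zarr")
  if (grepl("\\.n5/?$", lower)) return("n5")
  stop(sprintf("cannot infer image format of '%s'", path), call. = FALSE)
}

is_integral <- function(x, max_u16 = TRUE) {
  all(x == round(x)) && min(x) >= 0 && (!max_u16 || max(x) <= 65535)
}

write_image_tiff <- function(img, path) {
  d <- dim(img$data)
  rank <- length(d)
  if (rank > 3) {
    stop("TIFF output supports rank 2 or 3; use zarr/n5/npz for higher ranks",
         call. = FALSE)
  }
  pages <- if (rank == 2) list(img$data) else {
    lapply(seq_len(d[1]), function(i) array(img$data[i, , ], d[2:3]))
  }
  desc <- as.character(jsonlite::toJSON(
    list(axes = paste(img$axes, collapse = "")), auto_unbox = TRUE))
  if (is_integral(img$data)) {
    tiff_write_pages(path, pages, sample_format = 1L, bits = 16L,
                     description = desc)
  } else {
    tiff_write_pages(path, pages, sample_format = 3L, bits = 32L,
                     description = desc)
  }
}

write_image_zarr <- function(img, path, chunks = NULL) {
  d <- dim(img$data)
  if (is.null(chunks)) chunks <- pmin(d, 256L)
  dtype <- if (is_integral(img$data)) "<i4" else "<f8"
  store <- zarr_create(path, d, chunks = chunks, dtype = dtype,
                       attrs = list(axes = paste(img$axes, collapse = "")))
  zarr_write_sub(store, rep(0L, length(d)), img$data)
}

write_image_n5 <- function(img, path) {
  dtype <- if (is_integral(img$data)) "int32" else "float64"
  n5_write_array(path, img$data, img$axes, dtype = dtype)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a CSV spot table
#'
#' Accepts axis-letter headers (`z,y,x` in any canonical order) or the
#' positional style `axis-0, axis-1, ...` exported by some annotation tools,
#' which is mapped onto the trailing spatial axes (`axis-0` is the slowest).
#'
#' @param path CSV file with a header row.
#' @return a [spot_table()].
#' @export
read_spot_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  nms <- names(df)
  if (all(grepl("^axis-[0-9]+$", nms))) {
    k <- length(nms)
    ord <- order(as.integer(sub("^axis-", "", nms)))
    df <- df[, ord, drop = FALSE]
    names(df) <- tail(c("t", "c", "z", "y", "x"), k)
  } else if (!all(nms %in% AXIS_ORDER)) {
    bad <- setdiff(nms, AXIS_ORDER)
    stop(sprintf("unrecognized spot table column '%s'", bad[1]), call. = FALSE)
  }
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v) && !anyNA(df[[j]])) {
      bad <- which(is.na(v))[1]
      stop(sprintf("non-numeric value in column '%s', row %d",
                   names(df)[j], bad), call. = FALSE)
    }
    df[[j]] <- v
  }
  ord <- order(match(names(df), AXIS_ORDER))
  spot_table(df[, ord, drop = FALSE])
}

#' Write a CSV spot table
#'
#' Writes axis-letter headers (`y,x` or `z,y,x`).
#'
#' @param spots a [spot_table()].
#' @param path destination CSV path.
#' @return invisibly, `path`.
#' @export
write_spot_table <- function(spots, path) {
  utils::write.csv(as.data.frame(spots), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
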