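# Minimal Zarr v2 directory-store backend (level-0 array only).
#
# Shapes in the on-disk metadata are C-order (slowest axis first) and match
# the ImageND axis order, so a (z, y, x) image is stored with shape
# (nz, ny, nx) and x fastest on disk. Chunks are raw little-endian by
# default; zlib-compressed chunks are also read and written
# (compressor id "zlib", as produced by common Zarr writers).

ZARR_DTYPES <- list(
  "<f8" = list(what = "double",  size = 8L),
  "<f4" = list(what = "double",  size = 4L),
  "<u2" = list(what = "integer", size = 2L),
  "<i4" = list(what = "integer", size = 4L),
  "|u1" = list(what = "integer", size = 1L)
)

zarr_dtype_for <- function(data) {
  if (is.double(data)) "<f8" else "<i4"
}

#' Create a Zarr v2 array store
#'
#' @param path directory to create (a `.zarray` file is written inside).
#' @param shape integer extents, slowest axis first (matches `ImageND` axes).
#' @param chunks chunk extents per axis; defaults to the full shape.
#' @param dtype one of `"<f8"`, `"<f4"`, `"<u2"`, `"<i4"`, `"|u1"`.
#' @param fill_value fill for never-written chunks.
#' @param compressor `NULL` for raw chunks or `"zlib"`.
#' @param attrs named list stored as `.zattrs` (axis labels etc.).
#' @return a zarr store handle (list), also returned by [zarr_open()].
#' @export
zarr_create <- function(path, shape, chunks = NULL, dtype = "<f8",
                        fill_value = 0, compressor = NULL, attrs = list()) {
  if (is.null(chunks)) chunks <- shape
  stopifnot(length(chunks) == length(shape), all(chunks >= 1))
  if (!dtype %in% names(ZARR_DTYPES)) stop("unsupported zarr dtype: ", dtype)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    zarr_format = 2L,
    shape = as.integer(shape),
    chunks = as.integer(chunks),
    dtype = dtype,
    compressor = if (is.null(compressor)) NULL else
      list(id = "zlib", level = 5L),
    fill_value = fill_value,
    order = "C",
    filters = NULL,
    dimension_separator = "."
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null",
                              digits = NA),
             file.path(path, ".zarray"))
  if (length(attrs)) {
    writeLines(jsonlite::toJSON(attrs, auto_unbox = TRUE, digits = NA),
               file.path(path, ".zattrs"))
  }
  zarr_open(path)
}

#' Open an existing Zarr v2 array store
#' @param path store directory containing `.zarray`.
#' @return a store handle with `shape`, `chunks`, `dtype`, `attrs`.
#' @export
zarr_open <- function(path) {
  zf <- file.path(path, ".zarray")
  if (!file.exists(zf)) stop("not a zarr array store: ", path, call. = FALSE)
  meta <- jsonlite::fromJSON(zf, simplifyVector = TRUE)
  if (!is.null(meta$order) && meta$order != "C") {
    stop("only C-order zarr arrays are supported", call. = FALSE)
  }
  comp <- NULL
  if (!is.null(meta$compressor) && length(meta$compressor)) {
    if (!identical(meta$compressor$id, "zlib")) {
      stop("unsupported zarr compressor: ", meta$compressor$id, call. = FALSE)
    }
    comp <- "zlib"
  }
  attrs <- list()
  af <- file.path(path, ".zattrs")
  if (file.exists(af)) attrs <- jsonlite::fromJSON(af, simplifyVector = TRUE)
  structure(list(path = path, shape = as.integer(meta$shape),
                 chunks = as.integer(meta$chunks), dtype = meta$dtype,
                 fill_value = if (is.null(meta$fill_value)) 0 else meta$fill_value,
                 compressor = comp, attrs = attrs),
            class = "zarr_store")
}

zarr_chunk_file <- function(store, cidx) {
  file.path(store$path, paste(cidx, collapse = "."))
}

zarr_read_chunk <- function(store, cidx) {
  f <- zarr_chunk_file(store, cidx)
  cd <- store$chunks
  if (!file.exists(f)) {
    return(array(store$fill_value, rev(cd)))
  }
  dt <- ZARR_DTYPES[[store$dtype]]
  bytes <- readBin(f, "raw", file.info(f)$size)
  if (!is.null(store$compressor)) {
    bytes <- memDecompress(bytes, type = "gzip")
  }
  vals <- readBin(bytes, dt$what, n = prod(cd), size = dt$size,
                  endian = "little",
                  signed = !(store$dtype %in% c("<u2", "|u1")))
  array(vals, rev(cd))  # C order: last metadata axis fastest
}

zarr_write_chunk <- function(store, cidx, arr_rev) {
  # arr_rev has dim rev(chunks): fastest axis first, matching C byte order
  dt <- ZARR_DTYPES[[store$dtype]]
  vals <- as.vector(arr_rev)
  if (dt$what == "integer") vals <- as.integer(round(vals))
  bytes <- writeBin(vals, raw(), size = dt$size, endian = "little")
  if (!is.null(store$compressor)) {
    bytes <- memCompress(bytes, type = "gzip")
  }
  writeBin(bytes, zarr_chunk_file(store, cidx))
}

#' Read a rectangular sub-array from a Zarr store
#' @param store a handle from [zarr_open()].
#' @param offset 0-based per-axis start, in metadata (axis) order.
#' @param size per-axis extents to read.
#' @return an array of dimension `size`.
#' @export
zarr_read_sub <- function(store, offset, size) {
  nd <- length(store$shape)
  stopifnot(length(offset) == nd, length(size) == nd)
  out <- array(store$fill_value, size)
  c_lo <- offset %/% store$chunks
  c_hi <- (offset + size - 1L) %/% store$chunks
  grid <- expand.grid(lapply(seq_len(nd), function(i) c_lo[i]:c_hi[i]))
  for (r in seq_len(nrow(grid))) {
    cidx <- as.integer(grid[r, ])
    ch <- zarr_read_chunk(store, cidx)      # dim rev(chunks)
    ch <- aperm(ch, rev(seq_len(nd)))       # back to axis order
    c0 <- cidx * store$chunks               # chunk origin, 0-based
    lo <- pmax(offset, c0)
    hi <- pmin(offset + size, c0 + store$chunks)
    src <- lapply(seq_len(nd), function(i) (lo[i] - c0[i] + 1L):(hi[i] - c0[i]))
    dst <- lapply(seq_len(nd), function(i) (lo[i] - offset[i] + 1L):(hi[i] - offset[i]))
    piece <- do.call(`[`, c(list(ch), src, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), dst, list(value = piece)))
  }
  out
}

#' Write a rectangular sub-array into a Zarr store
#'
#' Partially covered chunks are read, patched and rewritten.
#'
#' @inheritParams zarr_read_sub
#' @param arr array to write at `offset`.
#' @return invisibly, the store handle.
#' @export
zarr_write_sub <- function(store, offset, arr) {
  nd <- length(store$shape)
  size <- dim(arr)
  if (is.null(size)) size <- length(arr)
  stopifnot(length(offset) == nd, length(size) == nd)
  c_lo <- offset %/% store$chunks
  c_hi <- (offset + size - 1L) %/% store$chunks
  grid <- expand.grid(lapply(seq_len(nd), function(i) c_lo[i]:c_hi[i]))
  for (r in seq_len(nrow(grid))) {
    cidx <- as.integer(grid[r, ])
    c0 <- cidx * store$chunks
    lo <- pmax(offset, c0)
    hi <- pmin(offset + size, c0 + store$chunks)
    full <- all(lo == c0) && all(hi == c0 + store$chunks)
    ch <- if (full) array(store$fill_value, store$chunks) else {
      aperm(zarr_read_chunk(store, cidx), rev(seq_len(nd)))
    }
    src <- lapply(seq_len(nd), function(i) (lo[i] - offset[i] + 1L):(hi[i] - offset[i]))
    dst <- lapply(seq_len(nd), function(i) (lo[i] - c0[i] + 1L):(hi[i] - c0[i]))
    piece <- do.call(`[`, c(list(arr), src, list(drop = FALSE)))
    ch <- do.call(`[<-`, c(list(ch), dst, list(value = piece)))
    zarr_write_chunk(store, cidx, aperm(ch, rev(seq_len(nd))))
  }
  invisible(store)
}

#' Read an entire Zarr array
#' @inheritParams zarr_read_sub
#' @return the full array.
#' @export
zarr_read_full <- function(store) {
  zarr_read_sub(store, rep(0L, length(store$shape)), store$shape)
}

is_zarr_path <- function(path) {
  dir.exists(path) && file.exists(file.path(path, ".zarray"))
}
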