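# Minimal N5 dataset backend (raw compression, single dataset directory).
#
# N5 lists dimensions fastest axis first, i.e. reversed with respect to the
# C-order shape used in Zarr metadata and in ImageND axes. Block files live
# at nested paths "i/j/..." indexed along the N5 dimension order, and every
# block carries a big-endian header (mode, ndim, block extents) followed by
# big-endian payload.

N5_DTYPES <- list(
  float64 = list(what = "double",  size = 8L),
  float32 = list(what = "double",  size = 4L),
  uint16  = list(what = "integer", size = 2L),
  int32   = list(what = "integer", size = 4L),
  uint8   = list(what = "integer", size = 1L)
)

n5_dtype_for <- function(data) if (is.double(data)) "float64" else "int32"

n5_write_array <- function(path, arr, axes, dtype = NULL, block_size = NULL) {
  d <- dim(arr)
  nd <- length(d)
  if (is.null(dtype)) dtype <- n5_dtype_for(arr)
  if (!dtype %in% names(N5_DTYPES)) stop("unsupported N5 dataType: ", dtype)
  dims_n5 <- rev(d)                      # fastest first
  if (is.null(block_size)) block_size <- pmin(dims_n5, 256L)
  block_size <- as.integer(block_size)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  attrs <- list(dimensions = as.integer(dims_n5),
                blockSize = block_size,
                dataType = dtype,
                compression = list(type = "raw"),
                axes = paste(axes, collapse = ""))
  writeLines(jsonlite::toJSON(attrs, auto_unbox = TRUE, digits = NA),
             file.path(path, "attributes.json"))
  dt <- N5_DTYPES[[dtype]]
  # iterate block grid in N5 dimension order
  ngrid <- (dims_n5 + block_size - 1L) %/% block_size
  grid <- expand.grid(lapply(ngrid, function(n) 0:(n - 1L)))
  # N5 dimension k corresponds to R axis nd + 1 - k
  for (r in seq_len(nrow(grid))) {
    g <- as.integer(grid[r, ])             # block grid coords, N5 order
    lo <- g * block_size                   # 0-based, N5 order
    hi <- pmin(lo + block_size, dims_n5)
    bs <- hi - lo                          # actual block extents, N5 order
    # R-axis index ranges: R axis j corresponds to N5 axis nd+1-j
    idx <- lapply(seq_len(nd), function(j) {
      k <- nd + 1L - j
      (lo[k] + 1L):(hi[k])
    })
    piece <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
    # payload order: N5 dim 1 fastest == R axis nd fastest -> aperm to rev
    vals <- as.vector(aperm(piece, rev(seq_len(nd))))
    if (dt$what == "integer") vals <- as.integer(round(vals))
    f <- file.path(path, paste(g, collapse = "/"))
    dir.create(dirname(f), recursive = TRUE, showWarnings = FALSE)
    con <- file(f, "wb")
    writeBin(c(0L, nd), con, size = 2L, endian = "big")
    writeBin(as.integer(bs), con, size = 4L, endian = "big")
    writeBin(vals, con, size = dt$size, endian = "big")
    close(con)
  }
  invisible(path)
}

n5_read_array <- function(path) {
  af <- file.path(path, "attributes.json")
  if (!file.exists(af)) stop("not an N5 dataset: ", path, call. = FALSE)
  attrs <- jsonlite::fromJSON(af, simplifyVector = TRUE)
  dims_n5 <- as.integer(attrs$dimensions)
  block_size <- as.integer(attrs$blockSize)
  dtype <- attrs$dataType
  if (!dtype %in% names(N5_DTYPES)) {
    stop("unsupported N5 dataType: ", dtype, call. = FALSE)
  }
  if (!is.null(attrs$compression$type) && attrs$compression$type != "raw") {
    stop("unsupported N5 compression: ", attrs$compression$type, call. = FALSE)
  }
  dt <- N5_DTYPES[[dtype]]
  nd <- length(dims_n5)
  d <- rev(dims_n5)
  out <- array(0, d)
  ngrid <- (dims_n5 + block_size - 1L) %/% block_size
  grid <- expand.grid(lapply(ngrid, function(n) 0:(n - 1L)))
  for (r in seq_len(nrow(grid))) {
    g <- as.integer(grid[r, ])
    f <- file.path(path, paste(g, collapse = "/"))
    lo <- g * block_size
    hi <- pmin(lo + block_size, dims_n5)
    bs <- hi - lo
    if (!file.exists(f)) next
    con <- file(f, "rb")
    hdr <- readBin(con, "integer", 2L, size = 2L, endian = "big")
    bdims <- readBin(con, "integer", hdr[2], size = 4L, endian = "big")
    vals <- readBin(con, dt$what, prod(bdims), size = dt$size, endian = "big",
                    signed = !(dtype %in% c("uint16", "uint8")))
    close(con)
    block <- array(vals, bdims)                     # N5 dim 1 fastest
    block <- aperm(block, rev(seq_len(nd)))         # to R axis order
    idx <- lapply(seq_len(nd), function(j) {
      k <- nd + 1L - j
      (lo[k] + 1L):(lo[k] + bdims[k])
    })
    out <- do.call(`[<-`, c(list(out), idx, list(value = block)))
  }
  axes <- if (!is.null(attrs$axes)) strsplit(attrs$axes, "")[[1]] else NULL
  list(data = out, axes = axes)
}

is_n5_path <- function(path) {
  dir.exists(path) && file.exists(file.path(path, "attributes.json")) &&
    !file.exists(file.path(path, ".zarray"))
}
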