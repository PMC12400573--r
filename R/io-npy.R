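# Minimal NPY / NPZ container support.
#
# NPY format 1.0: magic, ASCII header dict, raw little-endian payload.
# NPZ is a ZIP of NPY members; the image lives under the key "image". The
# writer emits stored (uncompressed) ZIP entries so no external zip binary
# is required; reading goes through utils::unzip (internal unzip).

npy_descr <- function(data) if (is.double(data)) "<f8" else "<i4"

NPY_DESCRS <- list(
  "<f8" = list(what = "double",  size = 8L),
  "<f4" = list(what = "double",  size = 4L),
  "<i8" = list(what = "double",  size = 8L),  # read as double (R has no int64)
  "<i4" = list(what = "integer", size = 4L),
  "<u2" = list(what = "integer", size = 2L),
  "|u1" = list(what = "integer", size = 1L)
)

npy_bytes <- function(arr) {
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  nd <- length(d)
  descr <- npy_descr(arr)
  shape_str <- if (nd == 1) sprintf("(%d,)", d) else
    sprintf("(%s)", paste(d, collapse = ", "))
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    descr, shape_str)
  # pad so that magic(6) + version(2) + hlen(2) + header is a multiple of 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  header <- paste0(header, strrep(" ", pad), "\n")
  vals <- if (nd > 1) as.vector(aperm(arr, rev(seq_len(nd)))) else as.vector(arr)
  dt <- NPY_DESCRS[[descr]]
  if (dt$what == "integer") vals <- as.integer(round(vals))
  c(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)),
    writeBin(nchar(header), raw(), size = 2L, endian = "little"),
    charToRaw(header),
    writeBin(vals, raw(), size = dt$size, endian = "little"))
}

npy_parse <- function(bytes) {
  if (!identical(bytes[1:6], as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59)))) {
    stop("not an NPY file", call. = FALSE)
  }
  major <- as.integer(bytes[7])
  if (major == 1) {
    hlen <- readBin(bytes[9:10], "integer", size = 2L, endian = "little",
                    signed = FALSE)
    hstart <- 11L
  } else {
    hlen <- readBin(bytes[9:12], "integer", size = 4L, endian = "little")
    hstart <- 13L
  }
  header <- rawToChar(bytes[hstart:(hstart + hlen - 1L)])
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  dt <- NPY_DESCRS[[descr]]
  if (is.null(dt)) stop("unsupported NPY dtype: ", descr, call. = FALSE)
  payload <- bytes[(hstart + hlen):length(bytes)]
  vals <- readBin(payload, dt$what, prod(shape), size = dt$size,
                  endian = "little",
                  signed = !(descr %in% c("<u2", "|u1")))
  nd <- length(shape)
  arr <- if (fortran) array(vals, shape) else
    aperm(array(vals, rev(shape)), rev(seq_len(nd)))
  arr
}

# --- stored-entry ZIP writer -------------------------------------------------

zip_store <- function(path, members) {
  # members: named list of raw vectors
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(members))
  crcs <- numeric(length(members))
  nms <- names(members)
  pos <- 0L
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
  u32 <- function(x) {
    # unsigned 32-bit little-endian via two 16-bit halves
    lo <- x %% 65536
    hi <- x %/% 65536
    c(u16(lo), u16(hi))
  }
  for (i in seq_along(members)) {
    data <- members[[i]]
    name <- charToRaw(nms[i])
    crcs[i] <- crc32_cpp(data)
    offsets[i] <- pos
    hdr <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), u16(20), u16(0), u16(0),
             u16(0), u16(0), u32(crcs[i]), u32(length(data)),
             u32(length(data)), u16(length(name)), u16(0))
    writeBin(hdr, con)
    writeBin(name, con)
    writeBin(data, con)
    pos <- pos + length(hdr) + length(name) + length(data)
  }
  cd_start <- pos
  cd_len <- 0L
  for (i in seq_along(members)) {
    data <- members[[i]]
    name <- charToRaw(nms[i])
    rec <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)), u16(20), u16(20), u16(0),
             u16(0), u16(0), u16(0), u32(crcs[i]), u32(length(data)),
             u32(length(data)), u16(length(name)), u16(0), u16(0), u16(0),
             u16(0), u32(0), u32(offsets[i]))
    writeBin(rec, con)
    writeBin(name, con)
    cd_len <- cd_len + length(rec) + length(name)
  }
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), u16(0), u16(0),
            u16(length(members)), u16(length(members)), u32(cd_len),
            u32(cd_start), u16(0))
  writeBin(eocd, con)
  invisible(path)
}

npz_write <- function(path, arrays) {
  members <- lapply(arrays, npy_bytes)
  names(members) <- paste0(names(arrays), ".npy")
  zip_store(path, members)
}

npz_read <- function(path, key = NULL) {
  exdir <- tempfile("npz")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  nms <- sub("\\.npy$", "", basename(files))
  if (!is.null(key)) {
    f <- files[nms == key]
    if (!length(f)) stop("NPZ has no member '", key, "'", call. = FALSE)
    return(npy_parse(readBin(f, "raw", file.info(f)$size)))
  }
  out <- lapply(files, function(f) npy_parse(readBin(f, "raw", file.info(f)$size)))
  names(out) <- nms
  out
}
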