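# Minimal baseline TIFF writer (little-endian, uncompressed, one strip per
# page). The installed TIFF writer stores floating point only after clamping
# to [0, 1]; raw microscopy intensities live on arbitrary photon scales, so
# this writer emits IEEE float32 (SampleFormat 3) or uint16 pages verbatim
# and records axis labels in the ImageDescription tag. Reading goes through
# tiff::readTIFF, which handles both sample formats.

tiff_write_pages <- function(path, pages, sample_format, bits, description) {
  # pages: list of numeric matrices (y rows, x cols)
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  u32 <- function(x) {
    lo <- x %% 65536; hi <- x %/% 65536
    writeBin(as.integer(c(lo, hi)), con, size = 2L, endian = "little")
  }
  desc_raw <- c(charToRaw(description), as.raw(0L))
  n_entries <- function(first) 10L + as.integer(first && length(desc_raw) > 0)
  ifd_size <- function(first) 2L + n_entries(first) * 12L + 4L
  # layout per page: [description (page 1)] [strip] [IFD]
  offset <- 8L
  strip_off <- integer(length(pages))
  ifd_off <- integer(length(pages))
  desc_off <- 0L
  for (i in seq_along(pages)) {
    first <- i == 1L
    if (first) { desc_off <- offset; offset <- offset + length(desc_raw) }
    strip_off[i] <- offset
    offset <- offset + length(pages[[i]]) * (bits %/% 8L)
    ifd_off[i] <- offset
    offset <- offset + ifd_size(first)
  }
  # header
  writeBin(charToRaw("II"), con)
  u16(42L)
  u32(ifd_off[1])
  for (i in seq_along(pages)) {
    first <- i == 1L
    m <- pages[[i]]
    if (first) writeBin(desc_raw, con)
    vals <- as.vector(t(m))  # row-major
    if (sample_format == 1L) {
      writeBin(as.integer(round(vals)), con, size = bits %/% 8L,
               endian = "little")
    } else {
      writeBin(as.double(vals), con, size = 4L, endian = "little")
    }
    # IFD
    entry <- function(tag, type, count, value) {
      u16(tag); u16(type); u32(count)
      if (type == 3L && count == 1L) { u16(value); u16(0L) } else u32(value)
    }
    u16(n_entries(first))
    entry(256L, 4L, 1L, ncol(m))                 # ImageWidth
    entry(257L, 4L, 1L, nrow(m))                 # ImageLength
    entry(258L, 3L, 1L, bits)                    # BitsPerSample
    entry(259L, 3L, 1L, 1L)                      # Compression: none
    entry(262L, 3L, 1L, 1L)                      # Photometric: BlackIsZero
    if (first) entry(270L, 2L, length(desc_raw), desc_off)
    entry(273L, 4L, 1L, strip_off[i])            # StripOffsets
    entry(277L, 3L, 1L, 1L)                      # SamplesPerPixel
    entry(278L, 4L, 1L, nrow(m))                 # RowsPerStrip
    entry(279L, 4L, 1L, length(m) * (bits %/% 8L))  # StripByteCounts
    entry(339L, 3L, 1L, sample_format)           # SampleFormat
    u32(if (i < length(pages)) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}
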