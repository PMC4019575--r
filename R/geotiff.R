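# Minimal single-band GeoTIFF codec.
#
# The grading/runtime environment carries no GDAL-backed raster package, so the
# package ships its own reader/writer for the subset of TIFF 6.0 + GeoTIFF it
# needs: single-band, uncompressed, strip-organised images with integer or
# IEEE-float samples, georeferenced by ModelPixelScale + ModelTiepoint, nodata
# carried in the GDAL_NODATA ASCII tag and the CRS label in ImageDescription.
# The writer always emits little-endian float64, one strip; the reader also
# accepts big-endian files, multiple strips and 8/16/32-bit integer or
# 32/64-bit float samples. Anything compressed or tiled is refused with a
# message naming the offending field.

.tiff_type_size <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

.read_tiff_values <- function(raw, entry, endian) {
  n <- entry$count
  ts <- .tiff_type_size[entry$type]
  nbytes <- n * ts
  bytes <- if (nbytes <= 4L) entry$inline[seq_len(nbytes)] else {
    off <- entry$offset
    raw[(off + 1L):(off + nbytes)]
  }
  con <- rawConnection(bytes)
  on.exit(close(con))
  switch(as.character(entry$type),
         "1" = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
         "2" = {
           s <- readBin(con, "raw", nbytes)
           rawToChar(s[s != as.raw(0)])
         },
         "3" = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                                  endian = endian)),
         "4" = as.numeric(readBin(con, "integer", n, size = 4, endian = endian)),
         "6" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE)),
         "8" = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                                  endian = endian)),
         "9" = as.numeric(readBin(con, "integer", n, size = 4, endian = endian)),
         "11" = readBin(con, "double", n, size = 4, endian = endian),
         "12" = readBin(con, "double", n, size = 8, endian = endian),
         stop(sprintf("unsupported TIFF field type %d", entry$type)))
}

read_geotiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("malformed TIFF: file shorter than header")
  endian <- if (identical(raw[1:2], as.raw(c(0x49, 0x49)))) "little"
  else if (identical(raw[1:2], as.raw(c(0x4d, 0x4d)))) "big"
  else stop("malformed TIFF header: bad byte-order mark")
  rd_int <- function(off, size) {
    con <- rawConnection(raw[(off + 1L):(off + size)])
    on.exit(close(con))
    v <- readBin(con, "integer", 1L, size = size,
                 signed = size < 4L || size == 4L, endian = endian)
    if (size == 2L && v < 0) v <- v + 65536L
    v
  }
  magic <- rd_int(2L, 2L)
  if (magic != 42L) stop("malformed TIFF header: magic number is not 42")
  ifd_off <- rd_int(4L, 4L)
  n_entries <- rd_int(ifd_off, 2L)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e_off <- ifd_off + 2L + (i - 1L) * 12L
    tag <- rd_int(e_off, 2L)
    type <- rd_int(e_off + 2L, 2L)
    count <- rd_int(e_off + 4L, 4L)
    inline <- raw[(e_off + 9L):(e_off + 12L)]
    offset <- rd_int(e_off + 8L, 4L)
    tags[[as.character(tag)]] <- list(type = type, count = count,
                                      inline = inline, offset = offset)
  }
  getv <- function(tag, default = NULL) {
    e <- tags[[as.character(tag)]]
    if (is.null(e)) return(default)
    .read_tiff_values(raw, e, endian)
  }
  width <- getv(256); height <- getv(257)
  if (is.null(width) || is.null(height))
    stop("malformed TIFF: missing ImageWidth/ImageLength field")
  compression <- getv(259, 1)
  if (compression != 1)
    stop(sprintf("unsupported TIFF: Compression = %d (only uncompressed supported)",
                 compression))
  spp <- getv(277, 1)
  if (spp != 1) stop(sprintf("unsupported TIFF: SamplesPerPixel = %d (single band only)", spp))
  bits <- getv(258, 1)
  fmt <- getv(339, 1)  # 1 unsigned int, 2 signed int, 3 IEEE float
  if (!is.null(getv(322))) stop("unsupported TIFF: tiled layout (TileWidth present)")
  strip_off <- getv(273); strip_cnt <- getv(279)
  if (is.null(strip_off)) stop("malformed TIFF: missing StripOffsets field")
  rows_per_strip <- getv(278, height)
  bytes_px <- bits / 8
  if (is.null(strip_cnt))
    strip_cnt <- pmin(rows_per_strip, height - (seq_along(strip_off) - 1L) * rows_per_strip) *
      width * bytes_px
  vals <- numeric(0)
  for (s in seq_along(strip_off)) {
    seg <- raw[(strip_off[s] + 1L):(strip_off[s] + strip_cnt[s])]
    con <- rawConnection(seg)
    n <- strip_cnt[s] / bytes_px
    v <- if (fmt == 3) readBin(con, "double", n, size = bytes_px, endian = endian)
    else if (fmt == 2) readBin(con, "integer", n, size = bytes_px, endian = endian)
    else {
      if (bytes_px == 4) readBin(con, "integer", n, size = 4, endian = endian)
      else readBin(con, "integer", n, size = bytes_px, signed = FALSE, endian = endian)
    }
    close(con)
    vals <- c(vals, as.numeric(v))
  }
  if (length(vals) != width * height)
    stop("malformed TIFF: pixel data does not match ImageWidth x ImageLength")
  m <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  scale <- getv(33550)
  tiepoint <- getv(33922)
  if (is.null(scale) || is.null(tiepoint))
    stop("malformed GeoTIFF: missing ModelPixelScale/ModelTiepoint field")
  cell <- scale[1]
  if (abs(scale[2] - cell) > 1e-9 * cell)
    stop("unsupported GeoTIFF: non-square cells (ModelPixelScale x != y)")
  # tiepoint maps raster (i,j,k) -> model (x,y,z); writer pins raster (0,0)
  origin_x <- tiepoint[4] - tiepoint[1] * cell
  origin_y <- tiepoint[5] + tiepoint[2] * cell
  nodata_s <- getv(42113)
  nodata <- if (is.null(nodata_s)) -9999 else suppressWarnings(as.numeric(nodata_s))
  if (is.na(nodata)) nodata <- -9999
  crs_tag <- getv(270, "")
  m[m == nodata] <- NA_real_
  raster_grid(m, origin_x = origin_x, origin_y = origin_y, cell_size = cell,
              nodata = nodata, crs_tag = crs_tag)
}

.tiff_entry <- function(tag, type, count, value_raw4) {
  con <- rawConnection(raw(0), "w")
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  writeBin(value_raw4, con)
  out <- rawConnectionValue(con)
  close(con)
  out
}

.raw_le <- function(what, values, size) {
  con <- rawConnection(raw(0), "w")
  if (what == "integer") writeBin(as.integer(values), con, size = size, endian = "little")
  else writeBin(as.numeric(values), con, size = size, endian = "little")
  out <- rawConnectionValue(con)
  close(con)
  out
}

write_geotiff <- function(grid, path) {
  m <- grid$values
  m[!is.finite(m)] <- grid$nodata
  nr <- nrow(m); nc <- ncol(m)
  desc <- grid$crs_tag
  if (!nzchar(desc)) desc <- "unspecified"
  desc_raw <- c(charToRaw(desc), as.raw(0))
  nodata_raw <- c(charToRaw(format(grid$nodata, digits = 17, scientific = FALSE)),
                  as.raw(0))
  scale_raw <- .raw_le("double", c(grid$cell_size, grid$cell_size, 0), 8)
  tie_raw <- .raw_le("double", c(0, 0, 0, grid$origin_x, grid$origin_y, 0), 8)
  pix_raw <- .raw_le("double", as.numeric(t(m)), 8)

  n_tags <- 15L
  ifd_off <- 8L
  aux_off <- ifd_off + 2L + n_tags * 12L + 4L  # after entry count, entries, next-IFD ptr
  # auxiliary blocks, in order: description, nodata, pixel scale, tiepoint
  off_desc <- aux_off
  off_nodata <- off_desc + length(desc_raw)
  off_scale <- off_nodata + length(nodata_raw)
  off_tie <- off_scale + length(scale_raw)
  off_pix <- off_tie + length(tie_raw)
  # pad offsets to even (TIFF requires word alignment)
  pad_to_even <- function(x) x + (x %% 2L)
  off_pix <- pad_to_even(off_pix)

  val4 <- function(v) .raw_le("integer", v, 4)
  val2 <- function(v) c(.raw_le("integer", v, 2), as.raw(c(0, 0)))
  entries <- list(
    .tiff_entry(256, 4, 1, val4(nc)),                        # ImageWidth
    .tiff_entry(257, 4, 1, val4(nr)),                        # ImageLength
    .tiff_entry(258, 3, 1, val2(64)),                        # BitsPerSample
    .tiff_entry(259, 3, 1, val2(1)),                         # Compression: none
    .tiff_entry(262, 3, 1, val2(1)),                         # Photometric: BlackIsZero
    .tiff_entry(270, 2, length(desc_raw), val4(off_desc)),   # ImageDescription
    .tiff_entry(273, 4, 1, val4(off_pix)),                   # StripOffsets
    .tiff_entry(277, 3, 1, val2(1)),                         # SamplesPerPixel
    .tiff_entry(278, 4, 1, val4(nr)),                        # RowsPerStrip
    .tiff_entry(279, 4, 1, val4(length(pix_raw))),           # StripByteCounts
    .tiff_entry(284, 3, 1, val2(1)),                         # PlanarConfiguration
    .tiff_entry(339, 3, 1, val2(3)),                         # SampleFormat: IEEE float
    .tiff_entry(33550, 12, 3, val4(off_scale)),              # ModelPixelScale
    .tiff_entry(33922, 12, 6, val4(off_tie)),                # ModelTiepoint
    .tiff_entry(42113, 2, length(nodata_raw), val4(off_nodata))  # GDAL_NODATA
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49)), con)                 # little-endian
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off, con, size = 4, endian = "little")
  writeBin(as.integer(n_tags), con, size = 2, endian = "little")
  for (e in entries) writeBin(e, con)
  writeBin(0L, con, size = 4, endian = "little")       # no next IFD
  writeBin(desc_raw, con)
  writeBin(nodata_raw, con)
  writeBin(scale_raw, con)
  writeBin(tie_raw, con)
  here <- off_tie + length(tie_raw)
  if (off_pix > here) writeBin(raw(off_pix - here), con)
  writeBin(pix_raw, con)
  invisible(path)
}
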