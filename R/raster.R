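# RasterGrid: the single-band georeferenced grid shared by every pipeline
# stage. Registration follows the north-up GeoTIFF convention: `origin_x`,
# `origin_y` are the coordinates of the grid's upper-left *corner*, row 1 is
# the northernmost row, and cell (r, c) is centred at
#   x = origin_x + (c - 0.5) * cell_size
#   y = origin_y - (r - 0.5) * cell_size
# Nodata is held as NA internally; the `nodata` sentinel is only used on disk.

#' Construct a RasterGrid
#'
#' @param values numeric matrix (rows = north to south); `NA` marks nodata.
#' @param origin_x,origin_y coordinates (metres) of the upper-left corner.
#' @param cell_size cell edge length in metres (must be > 0).
#' @param nodata sentinel written to / read from disk for missing cells.
#' @param crs_tag opaque coordinate-reference-system label carried through I/O.
#' @return an object of class `RasterGrid`.
#' @export
raster_grid <- function(values, origin_x = 0, origin_y = nrow(values) * cell_size,
                        cell_size = 1, nodata = -9999, crs_tag = "") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be a positive number")
  structure(list(values = values,
                 origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 cell_size = as.numeric(cell_size),
                 nodata = as.numeric(nodata),
                 crs_tag = as.character(crs_tag)),
            class = "RasterGrid")
}

#' @export
dim.RasterGrid <- function(x) dim(x$values)

#' @export
print.RasterGrid <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[is.finite(x$values)]
  cat(sprintf("RasterGrid: %d rows x %d cols @ %g m\n", d[1], d[2], x$cell_size))
  cat(sprintf("  origin (UL corner): %.3f, %.3f%s\n", x$origin_x, x$origin_y,
              if (nzchar(x$crs_tag)) paste0("  [", x$crs_tag, "]") else ""))
  if (length(v)) {
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g; %d nodata cells\n",
                min(v), mean(v), max(v), sum(!is.finite(x$values))))
  } else cat("  values: all nodata\n")
  invisible(x)
}

#' Are two grids co-registered?
#'
#' Same shape, origin and cell size (to 1e-9 relative tolerance). All layers
#' entering a joint analysis must satisfy this.
#' @param a,b `RasterGrid`s.
#' @return logical scalar.
#' @export
same_geometry <- function(a, b) {
  near <- function(u, v) isTRUE(abs(u - v) <= 1e-9 * max(1, abs(u), abs(v)))
  all(dim(a$values) == dim(b$values)) &&
    near(a$origin_x, b$origin_x) && near(a$origin_y, b$origin_y) &&
    near(a$cell_size, b$cell_size)
}

#' Cell indices for point coordinates
#'
#' @param grid a `RasterGrid`.
#' @param x,y point coordinates (metres).
#' @return list with integer vectors `row`, `col`; points outside the grid get
#'   `NA` indices.
#' @export
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1L
  bad <- row < 1L | row > nrow(grid$values) | col < 1L | col > ncol(grid$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Coordinates of cell centres
#'
#' @param grid a `RasterGrid`.
#' @param row,col integer indices (1-based, row 1 = north).
#' @return list with numeric vectors `x`, `y`.
#' @export
cell_centre <- function(grid, row, col) {
  list(x = grid$origin_x + (col - 0.5) * grid$cell_size,
       y = grid$origin_y - (row - 0.5) * grid$cell_size)
}

#' Clone a grid's geometry with new values
#' @param grid template `RasterGrid`.
#' @param values replacement matrix (same shape).
#' @return `RasterGrid`.
#' @export
with_values <- function(grid, values) {
  stopifnot(all(dim(values) == dim(grid$values)))
  g <- grid
  g$values <- values
  storage.mode(g$values) <- "double"
  g
}

# ---------------------------------------------------------------------------
# ESRI ASCII grid I/O

read_ascii_grid <- function(path) {
  head_lines <- readLines(path, n = 6L)
  known <- c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
             "yllcenter", "cellsize", "nodata_value")
  kv <- list()
  n_header <- 0L
  for (ln in head_lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    first_num <- suppressWarnings(as.numeric(parts[1]))
    if (!is.na(first_num)) break # start of the data block
    if (!tolower(parts[1]) %in% known)
      stop(sprintf("malformed ESRI ASCII header: unrecognised field '%s'",
                   parts[1]))
    if (length(parts) < 2 || suppressWarnings(is.na(as.numeric(parts[2]))))
      stop(sprintf("malformed ESRI ASCII header: field '%s' has no numeric value",
                   parts[1]))
    kv[[tolower(parts[1])]] <- as.numeric(parts[2])
    n_header <- n_header + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    stop(sprintf("malformed ESRI ASCII header: missing field(s) %s",
                 paste(miss, collapse = ", ")))
  if (!any(c("xllcorner", "xllcenter") %in% names(kv)))
    stop("malformed ESRI ASCII header: missing field xllcorner")
  if (!any(c("yllcorner", "yllcenter") %in% names(kv)))
    stop("malformed ESRI ASCII header: missing field yllcorner")
  nc <- as.integer(kv$ncols); nr <- as.integer(kv$nrows)
  cs <- kv$cellsize
  if (!is.finite(cs) || cs <= 0) stop("malformed ESRI ASCII header: cellsize must be > 0")
  xll <- if (!is.null(kv$xllcorner)) kv$xllcorner else kv$xllcenter - cs / 2
  yll <- if (!is.null(kv$yllcorner)) kv$yllcorner else kv$yllcenter - cs / 2
  nodata <- if (!is.null(kv$nodata_value)) kv$nodata_value else -9999
  vals <- scan(path, skip = n_header, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("ESRI ASCII body has %d values; header promises %d",
                 length(vals), nr * nc))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  raster_grid(m, origin_x = xll, origin_y = yll + nr * cs,
              cell_size = cs, nodata = nodata)
}

write_ascii_grid <- function(grid, path) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  yll <- grid$origin_y - nr * grid$cell_size
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", grid$origin_x),
           sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %.10g", grid$nodata))
  m <- grid$values
  m[!is.finite(m)] <- grid$nodata
  body <- apply(m, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Read a single-band raster
#'
#' Supports ESRI ASCII grids (`.asc`, `.agr`, `.grd`) and single-band
#' uncompressed GeoTIFF (`.tif`, `.tiff`). Format is chosen by file extension,
#' falling back to content sniffing.
#'
#' @param path file path.
#' @return a [raster_grid()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return(read_geotiff(path))
  if (ext %in% c("asc", "agr", "grd", "txt")) return(read_ascii_grid(path))
  # sniff: TIFF magic bytes
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) == 4L &&
      (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
       identical(magic[1:2], as.raw(c(0x4d, 0x4d)))))
    return(read_geotiff(path))
  read_ascii_grid(path)
}

#' Write a single-band raster
#'
#' @param grid a [raster_grid()].
#' @param path destination; `.asc` writes ESRI ASCII, `.tif`/`.tiff` writes an
#'   uncompressed float64 baseline GeoTIFF.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "RasterGrid"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) write_geotiff(grid, path) else write_ascii_grid(grid, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Feature stacks

#' Stack co-registered layers
#'
#' @param ... named `RasterGrid`s, or a single named list of them.
#' @return a `FeatureStack` (named list of layers + `names`).
#' @export
stack_layers <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) && !inherits(layers[[1]], "RasterGrid"))
    layers <- layers[[1]]
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("all layers must be named")
  if (anyDuplicated(names(layers)))
    stop("layer names must be unique")
  ref <- layers[[1]]
  for (nm in names(layers)) {
    if (!inherits(layers[[nm]], "RasterGrid"))
      stop(sprintf("layer '%s' is not a RasterGrid", nm))
    if (!same_geometry(ref, layers[[nm]]))
      stop(sprintf("layer '%s' is not co-registered with layer '%s'",
                   nm, names(layers)[1]))
  }
  structure(list(names = names(layers), layers = layers), class = "FeatureStack")
}

#' @export
print.FeatureStack <- function(x, ...) {
  d <- dim(x$layers[[1]]$values)
  cat(sprintf("FeatureStack: %d layers (%d x %d cells)\n", length(x$names), d[1], d[2]))
  cat(" ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Extract layer values at point locations
#'
#' @param stack a [stack_layers()] result.
#' @param x,y point coordinates (metres); must fall inside the raster extent.
#' @return `data.frame` with one row per point and one column per layer, plus
#'   a logical `complete` column (FALSE where any layer is nodata).
#' @export
sample_stack <- function(stack, x, y) {
  ref <- stack$layers[[1]]
  idx <- cell_index(ref, x, y)
  if (anyNA(idx$row))
    stop(sprintf("%d point(s) fall outside the raster extent", sum(is.na(idx$row))))
  lin <- cbind(idx$row, idx$col)
  out <- lapply(stack$layers, function(g) g$values[lin])
  df <- as.data.frame(out, check.names = FALSE)
  df$complete <- stats::complete.cases(df)
  df
}
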