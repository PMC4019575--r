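# Region-growing segmentation of the backscatter mosaic and vectorisation of
# the resulting segments to polygons.

#' Segmentation configuration
#' @param similarity_threshold final grey-level similarity threshold (the
#'   survey-scale default in the source workflow is 1).
#' @param area_threshold minimum segment size in pixels (survey-scale default
#'   2500; pixels, not square metres).
#' @param n_passes number of threshold-ramp passes; the working threshold
#'   grows geometrically (factor 2) up to `similarity_threshold`.
#' @return list of class `SegmentationConfig`.
#' @export
seg_config <- function(similarity_threshold = 1, area_threshold = 2500,
                       n_passes = 4) {
  stopifnot(similarity_threshold > 0, area_threshold > 0, n_passes >= 1)
  structure(list(similarity_threshold = similarity_threshold,
                 area_threshold = as.integer(area_threshold),
                 n_passes = as.integer(n_passes)),
            class = "SegmentationConfig")
}

.new_segment_set <- function(template, labels, areas, means) {
  lr <- with_values(template, labels)
  structure(list(label_raster = lr, areas = as.integer(areas),
                 means = as.numeric(means),
                 segment_ids = seq_along(areas)),
            class = "SegmentSet")
}

#' @export
print.SegmentSet <- function(x, ...) {
  cat(sprintf("SegmentSet: %d segments over %d valid pixels\n",
              length(x$areas), sum(x$areas)))
  invisible(x)
}

#' Region-growing segmentation
#'
#' Starts from single-pixel regions and recursively merges the adjacent
#' (4-connected) region pair with the most similar mean grey level, under a
#' threshold schedule that relaxes geometrically up to
#' `cfg$similarity_threshold`; regions smaller than `cfg$area_threshold`
#' pixels are then absorbed into their most similar neighbour. Region
#' similarity is the absolute difference of pixel-count-weighted region means;
#' ties are broken by lower region id, so repeated runs are identical. Nodata
#' pixels belong to no segment and segments never span nodata.
#'
#' @param mosaic single-band `RasterGrid` (typically the normalized mosaic or
#'   its 8-bit version).
#' @param cfg a [seg_config()].
#' @return a `SegmentSet`: `label_raster` (integer ids, NA over nodata),
#'   `areas` (pixel counts) and `means` (grey-level means) indexed by id.
#' @export
region_grow <- function(mosaic, cfg = seg_config()) {
  res <- .region_grow_cpp(mosaic$values, cfg$similarity_threshold,
                          cfg$area_threshold, cfg$n_passes)
  .new_segment_set(mosaic, res$labels, res$areas, res$means)
}

#' Build a SegmentSet directly from a class-id raster
#'
#' Each 4-connected patch of equal ids becomes a segment. Used to construct
#' oracle segmentations from a known habitat map (segments = true class
#' patches), bypassing the mosaic.
#'
#' @param class_raster integer-valued `RasterGrid` (NA = nodata).
#' @return a `SegmentSet`.
#' @export
segments_from_labels <- function(class_raster) {
  v <- class_raster$values
  nr <- nrow(v); nc <- ncol(v)
  lab <- matrix(NA_integer_, nr, nc)
  k <- 0L
  areas <- integer(0); sums <- numeric(0)
  for (start in which(!is.na(v))) {
    if (!is.na(lab[start])) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    npix <- 0L; s <- 0
    while (length(queue)) {
      i <- queue[length(queue)]
      queue <- queue[-length(queue)]
      npix <- npix + 1L; s <- s + v[i]
      r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
      for (j in c(if (r > 1L) i - 1L, if (r < nr) i + 1L,
                  if (c > 1L) i - nr, if (c < nc) i + nr)) {
        if (is.na(lab[j]) && !is.na(v[j]) && v[j] == v[i]) {
          lab[j] <- k
          queue <- c(queue, j)
        }
      }
    }
    areas[k] <- npix; sums[k] <- s
  }
  .new_segment_set(class_raster, lab, areas, sums / pmax(areas, 1L))
}

# ---------------------------------------------------------------------------
# Vectorisation: trace the boundary edges of each segment into closed rings.
# Ring vertices are grid-corner coordinates; exterior rings are
# counter-clockwise in map coordinates, holes clockwise (GeoJSON convention).

.trace_rings <- function(cell_rc, nr, nc) {
  # cell_rc: matrix [row, col] of member cells. Collect directed boundary
  # edges so that the segment interior lies to the left of each edge, then
  # chain them into closed rings.
  memb <- matrix(FALSE, nr + 2L, nc + 2L) # padded
  memb[cbind(cell_rc[, 1] + 1L, cell_rc[, 2] + 1L)] <- TRUE
  # corners indexed by (r, c) of the cell's top-left corner in grid units
  edges <- list()
  r <- cell_rc[, 1]; c <- cell_rc[, 2]
  # neighbour missing => boundary edge; direction keeps interior on the left
  # (in row/col space with row growing downward):
  up <- !memb[cbind(r, c + 1L)]
  dn <- !memb[cbind(r + 2L, c + 1L)]
  lf <- !memb[cbind(r + 1L, c)]
  rt <- !memb[cbind(r + 1L, c + 2L)]
  e <- rbind(
    if (any(up)) cbind(r[up] - 1L, c[up] - 1L, r[up] - 1L, c[up]),       # left->right along top
    if (any(rt)) cbind(r[rt] - 1L, c[rt], r[rt], c[rt]),                 # top->bottom along right
    if (any(dn)) cbind(r[dn], c[dn], r[dn], c[dn] - 1L),                 # right->left along bottom
    if (any(lf)) cbind(r[lf], c[lf] - 1L, r[lf] - 1L, c[lf] - 1L)        # bottom->top along left
  )
  if (is.null(e) || nrow(e) == 0L) return(list())
  key <- function(rr, cc) rr * (nc + 2L) + cc
  from <- key(e[, 1], e[, 2])
  used <- rep(FALSE, nrow(e))
  ord <- order(from, key(e[, 3], e[, 4]))
  e <- e[ord, , drop = FALSE]
  from <- from[ord]
  rings <- list()
  for (s in seq_len(nrow(e))) {
    if (used[s]) next
    ring <- matrix(0L, 0L, 2L)
    cur <- s
    repeat {
      used[cur] <- TRUE
      ring <- rbind(ring, e[cur, 1:2])
      nxt_key <- key(e[cur, 3], e[cur, 4])
      cand <- which(!used & from == nxt_key)
      if (!length(cand)) break
      # prefer the leftmost turn to keep rings simple at pinch corners:
      cur <- cand[1]
    }
    ring <- rbind(ring, ring[1, , drop = FALSE]) # close
    rings[[length(rings) + 1L]] <- ring
  }
  rings
}

.ring_signed_area <- function(ring_xy) {
  x <- ring_xy[, 1]; y <- ring_xy[, 2]
  n <- nrow(ring_xy)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Vectorise segments to polygons
#'
#' Each segment becomes one polygon (possibly with interior rings for fully
#' enclosed enclaves). Coordinates are map coordinates of cell corners, so the
#' polygon area equals `pixel count * cell_size^2` exactly.
#'
#' @param segment_set a [region_grow()] result.
#' @return list of polygons; each element has `segment_id`, `area_px`,
#'   `rings` (list of closed coordinate matrices, exterior first).
#' @export
vectorize <- function(segment_set) {
  lr <- segment_set$label_raster
  v <- lr$values
  nr <- nrow(v); nc <- ncol(v)
  out <- vector("list", length(segment_set$areas))
  for (sid in segment_set$segment_ids) {
    cells <- which(v == sid)
    rc <- cbind(((cells - 1L) %% nr) + 1L, ((cells - 1L) %/% nr) + 1L)
    rings_rc <- .trace_rings(rc, nr, nc)
    rings_xy <- lapply(rings_rc, function(m) {
      cbind(x = lr$origin_x + m[, 2] * lr$cell_size,
            y = lr$origin_y - m[, 1] * lr$cell_size)
    })
    if (length(rings_xy) > 1L) {
      a <- vapply(rings_xy, function(m) abs(.ring_signed_area(m)), 0)
      rings_xy <- rings_xy[order(-a)] # exterior (largest) first
    }
    out[[sid]] <- list(segment_id = sid, area_px = segment_set$areas[sid],
                       rings = rings_xy)
  }
  out
}

#' Write segment polygons to GeoJSON
#'
#' @param polygons result of [vectorize()].
#' @param path destination `.geojson` file.
#' @param crs_tag optional CRS label stored in a foreign member.
#' @export
write_polygons_geojson <- function(polygons, path, crs_tag = "") {
  features <- lapply(polygons, function(p) {
    coords <- lapply(p$rings, function(m) {
      lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
    })
    list(type = "Feature",
         properties = list(segment_id = p$segment_id, area_px = p$area_px),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  obj <- list(type = "FeatureCollection", features = features)
  if (nzchar(crs_tag)) obj$crs_tag <- crs_tag
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
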