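# Per-segment backscatter angular-response curves and their statistical
# features. Curves are compiled from the *pre-normalization* sample levels:
# angular normalization destroys exactly the angular information these
# features quantify.

#' Compile mean angular-response curves per segment
#'
#' Each sample is assigned to the segment whose label-raster cell contains its
#' position (cell membership, not polygon geometry, so every point belongs to
#' exactly one segment). Per segment and angle bin, the curve value is the
#' arithmetic mean of the levels in dB space. Samples falling outside all
#' segments are counted and dropped.
#'
#' @param samples pre-normalization sample `data.table`.
#' @param segment_set a [region_grow()] (or [segments_from_labels()]) result.
#' @param bin_width angle bin width in degrees; bins are centred on multiples
#'   of the width.
#' @return list of `ARCurve` objects (one per segment with data): each has
#'   `segment_id`, `bin_centres`, `mean_dB`, `counts`. Attribute
#'   `outside` counts samples outside all segments.
#' @export
compile_ar_curves <- function(samples, segment_set, bin_width = 1) {
  lr <- segment_set$label_raster
  idx <- cell_index(lr, samples$x, samples$y)
  sid <- rep(NA_integer_, nrow(samples))
  inb <- !is.na(idx$row)
  sid[inb] <- lr$values[cbind(idx$row[inb], idx$col[inb])]
  outside <- sum(is.na(sid))
  dt <- data.table(sid = sid, bin = as.integer(round(samples$angle / bin_width)),
                   level = samples$level)[!is.na(sid)]
  agg <- dt[, .(mean_dB = mean(level), n = .N), by = .(sid, bin)]
  setorder(agg, sid, bin)
  present <- sort(unique(agg$sid))
  empty <- setdiff(segment_set$segment_ids, present)
  if (length(empty))
    warning(sprintf("no samples in segment(s) %s; curve(s) omitted",
                    paste(empty, collapse = ", ")))
  curves <- lapply(present, function(s) {
    a <- agg[sid == s]
    structure(list(segment_id = s,
                   bin_centres = a$bin * bin_width,
                   mean_dB = a$mean_dB,
                   counts = a$n),
              class = "ARCurve")
  })
  attr(curves, "outside") <- outside
  curves
}

#' @export
print.ARCurve <- function(x, ...) {
  cat(sprintf("ARCurve segment %d: %d bins over %.0f-%.0f deg, %d samples\n",
              x$segment_id, length(x$bin_centres), min(x$bin_centres),
              max(x$bin_centres), sum(x$counts)))
  invisible(x)
}

.sample_skewness <- function(v) {
  m2 <- mean((v - mean(v))^2)
  if (m2 <= 0) return(NA_real_)
  mean((v - mean(v))^3) / m2^1.5
}

.sample_kurtosis <- function(v) {
  m2 <- mean((v - mean(v))^2)
  if (m2 <= 0) return(NA_real_)
  mean((v - mean(v))^4) / m2^2 # non-excess: Gaussian -> 3
}

#' Statistical features of an angular-response curve
#'
#' Over the populated bins within `[angle_lo, angle_hi]`: mean of the per-bin
#' mean levels, ordinary least-squares slope of level on angle, and sample
#' skewness / kurtosis (moment estimators; kurtosis is non-excess, so a
#' Gaussian gives 3) of the per-bin mean levels. Statistics are attributes of
#' the curve, not of the raw samples.
#'
#' @param curve an `ARCurve`.
#' @param angle_lo,angle_hi incidence-angle band, degrees (default 30-50).
#' @param min_bins minimum populated bins required (default 5); fewer marks
#'   the feature set undefined.
#' @return list of class `ARFeatures` with `segment_id`, `ar_mean`,
#'   `ar_slope`, `ar_skewness`, `ar_kurtosis`, `defined`. Skewness/kurtosis
#'   are `NA` for degenerate (zero-variance) curves.
#' @export
ar_features <- function(curve, angle_lo = 30, angle_hi = 50, min_bins = 5) {
  keep <- curve$bin_centres >= angle_lo & curve$bin_centres <= angle_hi
  th <- curve$bin_centres[keep]
  v <- curve$mean_dB[keep]
  if (length(v) < min_bins) {
    return(structure(list(segment_id = curve$segment_id, ar_mean = NA_real_,
                          ar_slope = NA_real_, ar_skewness = NA_real_,
                          ar_kurtosis = NA_real_, defined = FALSE),
                     class = "ARFeatures"))
  }
  slope <- sum((th - mean(th)) * (v - mean(v))) / sum((th - mean(th))^2)
  structure(list(segment_id = curve$segment_id,
                 ar_mean = mean(v),
                 ar_slope = slope,
                 ar_skewness = .sample_skewness(v),
                 ar_kurtosis = .sample_kurtosis(v),
                 defined = TRUE),
            class = "ARFeatures")
}

#' Angular-response features for every segment
#' @param curves result of [compile_ar_curves()].
#' @param ... passed to [ar_features()].
#' @return `data.frame` with one row per curve.
#' @export
ar_features_table <- function(curves, ...) {
  rows <- lapply(curves, function(cu) {
    f <- ar_features(cu, ...)
    data.frame(segment_id = f$segment_id, ar_mean = f$ar_mean,
               ar_slope = f$ar_slope, ar_skewness = f$ar_skewness,
               ar_kurtosis = f$ar_kurtosis, defined = f$defined)
  })
  do.call(rbind, rows)
}

#' Rasterise per-segment features back onto the grid
#'
#' Every pixel of a segment carries the segment's feature value; pixels of
#' segments with undefined features (or without curves) become nodata.
#'
#' @param segment_set a `SegmentSet`.
#' @param features a [ar_features_table()] data.frame.
#' @param template co-registered `RasterGrid` defining output geometry.
#' @return named list of four `RasterGrid`s: `ar_mean`, `ar_slope`,
#'   `ar_skew`, `ar_kurt`.
#' @export
rasterize_features <- function(segment_set, features, template = segment_set$label_raster) {
  lr <- segment_set$label_raster
  stopifnot(same_geometry(lr, template))
  n_seg <- max(segment_set$segment_ids)
  one <- function(col) {
    lut <- rep(NA_real_, n_seg)
    ok <- features$defined & is.finite(features[[col]])
    lut[features$segment_id[ok]] <- features[[col]][ok]
    with_values(template, matrix(lut[lr$values], nrow(lr$values), ncol(lr$values)))
  }
  list(ar_mean = one("ar_mean"), ar_slope = one("ar_slope"),
       ar_skew = one("ar_skewness"), ar_kurt = one("ar_kurtosis"))
}
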