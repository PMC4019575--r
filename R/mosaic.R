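# Angular-dependence compensation and mosaic gridding.
#
# All averaging is done in dB space: the per-segment angular-response curves
# are defined as dB-domain means, and the mosaic follows the same convention
# for coherence.

#' Normalization configuration
#' @param window_pings sliding window length in consecutive pings (default 25).
#' @param ref_angle reference incidence angle in degrees (default 30).
#' @param angle_bin angle bin width in degrees (default 1; bins centred on
#'   multiples of the width).
#' @return list of class `NormalizationConfig`.
#' @export
norm_config <- function(window_pings = 25, ref_angle = 30, angle_bin = 1) {
  stopifnot(window_pings >= 1, angle_bin > 0, ref_angle > 0)
  structure(list(window_pings = as.integer(window_pings),
                 ref_angle = ref_angle, angle_bin = angle_bin),
            class = "NormalizationConfig")
}

#' Statistically compensate the angular dependence of backscatter samples
#'
#' For each sample, the mean level of its angle bin within a centred sliding
#' window of `window_pings` consecutive pings (same survey line; truncated at
#' line ends) is subtracted, and the window's mean level at the reference
#' angle bin added back. On a homogeneous seabed this flattens any angular law
#' to the reference-angle level; across seabed types the contrast at the
#' reference angle is preserved.
#'
#' Samples whose window contains no reference-angle observations are dropped
#' and counted in the `"dropped"` attribute.
#'
#' @param samples sample `data.table` (see [read_samples()]).
#' @param cfg a [norm_config()].
#' @return samples with `level` replaced by the normalized level.
#' @export
angular_normalize <- function(samples, cfg = norm_config()) {
  dt <- as.data.table(samples)
  dt[, `.bin` := as.integer(round(angle / cfg$angle_bin))]
  ref_bin <- as.integer(round(cfg$ref_angle / cfg$angle_bin))
  half <- (cfg$window_pings - 1L) %/% 2L
  dt[, `.row` := .I]
  out <- vector("list", length(unique(dt$line_id)))
  li <- 0L
  for (ln in sort(unique(dt$line_id))) {
    sub <- dt[line_id == ln]
    pings <- sort(unique(sub$ping_id))
    P <- length(pings)
    pidx <- match(sub$ping_id, pings)
    bins <- sort(unique(sub$`.bin`))
    bidx <- match(sub$`.bin`, bins)
    B <- length(bins)
    S <- matrix(0, P, B); C <- matrix(0, P, B)
    ij <- cbind(pidx, bidx)
    agg <- sub[, .(s = sum(level), n = .N), by = .(pidx = pidx, bidx = bidx)]
    S[cbind(agg$pidx, agg$bidx)] <- agg$s
    C[cbind(agg$pidx, agg$bidx)] <- agg$n
    cs_S <- apply(S, 2L, cumsum); cs_C <- apply(C, 2L, cumsum)
    cs_S <- rbind(0, cs_S); cs_C <- rbind(0, cs_C)
    lo <- pmax(pidx - half, 1L); hi <- pmin(pidx + half + (cfg$window_pings - 1L) %% 2L, P)
    win_mean <- function(b) {
      (cs_S[cbind(hi + 1L, b)] - cs_S[cbind(lo, b)]) /
        (cs_C[cbind(hi + 1L, b)] - cs_C[cbind(lo, b)])
    }
    own_mean <- win_mean(bidx)
    rb <- match(ref_bin, bins)
    ref_mean <- if (is.na(rb)) rep(NaN, nrow(sub)) else win_mean(rep(rb, nrow(sub)))
    sub[, level := level - own_mean + ref_mean]
    li <- li + 1L
    out[[li]] <- sub
  }
  res <- rbindlist(out[seq_len(li)])
  setorder(res, `.row`)
  dropped <- sum(!is.finite(res$level))
  if (dropped > 0)
    message(sprintf("angular_normalize: dropped %d sample(s) with no reference-angle support in their window", dropped))
  res <- res[is.finite(level)]
  res[, c(".bin", ".row") := NULL]
  setattr(res, "dropped", dropped)
  res[]
}

#' Grid normalized samples into a backscatter mosaic
#'
#' Cell value = dB-domain mean of the normalized levels of all samples whose
#' position falls in the cell; cells with no samples are nodata.
#'
#' @param samples normalized sample `data.table`.
#' @param template `RasterGrid` defining the output geometry.
#' @return `RasterGrid` mosaic; attribute `counts` holds the per-cell
#'   contributing-sample counts (matrix).
#' @export
grid_mosaic <- function(samples, template) {
  idx <- cell_index(template, samples$x, samples$y)
  keep <- !is.na(idx$row)
  vals <- matrix(NA_real_, nrow(template$values), ncol(template$values))
  counts <- matrix(0L, nrow(template$values), ncol(template$values))
  if (!any(keep)) {
    warning("grid_mosaic: no samples fall inside the template; all-nodata mosaic")
    g <- with_values(template, vals)
    attr(g, "counts") <- counts
    return(g)
  }
  cell <- (idx$col[keep] - 1L) * nrow(vals) + idx$row[keep]
  dt <- data.table(cell = cell, level = samples$level[keep])
  agg <- dt[, .(m = mean(level), n = .N), by = cell]
  vals[agg$cell] <- agg$m
  counts[agg$cell] <- agg$n
  g <- with_values(template, vals)
  attr(g, "counts") <- counts
  g
}

#' Quantise a mosaic to 8-bit grey levels
#'
#' Linear map of `[lo_dB, hi_dB]` to `[0, 255]`, rounded half-up and clipped;
#' nodata preserved. Defaults for the scaling bounds are the 1st and 99th
#' percentiles of the mosaic.
#'
#' @param mosaic dB mosaic `RasterGrid`.
#' @param lo_dB,hi_dB scaling bounds (lo < hi).
#' @return `RasterGrid` of integers 0-255 (stored as doubles; NA = nodata).
#' @export
to_8bit <- function(mosaic, lo_dB = NULL, hi_dB = NULL) {
  v <- mosaic$values
  if (is.null(lo_dB)) lo_dB <- quantile(v, 0.01, na.rm = TRUE, names = FALSE)
  if (is.null(hi_dB)) hi_dB <- quantile(v, 0.99, na.rm = TRUE, names = FALSE)
  if (!(lo_dB < hi_dB)) stop("lo_dB must be < hi_dB")
  g <- floor((v - lo_dB) / (hi_dB - lo_dB) * 255 + 0.5)
  g <- pmin(pmax(g, 0), 255)
  with_values(mosaic, g)
}
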