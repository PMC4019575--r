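# Synthetic multibeam survey generator.
#
# The simulator states a small, explicit world: a smooth bathymetry surface
# (linear trend + Gaussian bumps), a habitat map built from depth bands
# crossed with a smoothed random field, and per-beam backscatter samples whose
# level follows a class-specific angular-response law
#
#   level(theta) = mu + slope * (theta - 40) + shape * ((25 - theta)/25)^2 [theta < 25]
#                  + N(0, noise_sd)
#
# i.e. exactly linear over the 30-50 degree feature band (so feature-recovery
# oracles have closed forms) with an optional near-nadir rise. Angles use a
# flat-seafloor approximation (incidence angle = beam steering angle), a mild
# assumption in the 30-50 degree band the features use.

#' Class angular-response models
#'
#' @param labels habitat class labels (subset of [habitat_classes]).
#' @param mu mean backscatter level at 40 degrees, dB (negative typical).
#' @param slope dB per degree over the linear 25-60 degree segment.
#' @param shape near-nadir rise amplitude in dB at nadir (0 disables).
#' @param noise_sd per-sample Gaussian noise, dB (>= 0).
#' @param min_separation smallest allowed |mu_i - mu_j| between classes.
#' @return `data.frame` with one row per class, class `ClassARModel`.
#' @export
ar_class_models <- function(labels, mu, slope, shape = 0, noise_sd = 0,
                            min_separation = 0) {
  n <- length(labels)
  df <- data.frame(label = labels, mu = mu, slope = slope,
                   shape = rep_len(shape, n), noise_sd = rep_len(noise_sd, n),
                   stringsAsFactors = FALSE)
  if (any(df$noise_sd < 0)) stop("noise_sd must be >= 0")
  if (n > 1 && min_separation > 0) {
    gaps <- abs(outer(df$mu, df$mu, "-"))
    if (min(gaps[upper.tri(gaps)]) < min_separation)
      stop(sprintf("class mean levels closer than min_separation = %g dB",
                   min_separation))
  }
  class(df) <- c("ClassARModel", "data.frame")
  df
}

#' Default class angular-response models
#'
#' The acoustic angular response is a property of the seabed substrate, not of
#' depth, so classes that share a substrate patch type across depth bands
#' (see [gen_habitat_map()]) share an AR model: habitat class is then jointly
#' determined by depth band (visible only to bathymetry) and substrate
#' (visible only to backscatter). Substrate mean levels are 6 dB apart
#' starting at -18 dB (rocky/algal reef is a strong scatterer; bare sediment
#' weak), slopes steepen by -0.10 dB/degree per substrate, with an 8 dB
#' near-nadir rise and speckle-like 5 dB per-sample noise.
#'
#' @param n_classes number of classes (1-7).
#' @param n_depth_bands depth bands of the paired habitat map (default 2);
#'   substrate type of class `k` is `((k - 1) %% ceiling(n_classes /
#'   n_depth_bands)) + 1`.
#' @return a [ar_class_models()] table.
#' @export
default_ar_models <- function(n_classes = 4, n_depth_bands = 2) {
  stopifnot(n_classes >= 1, n_classes <= length(habitat_classes))
  np <- ceiling(n_classes / max(1L, n_depth_bands))
  substrate <- ((seq_len(n_classes) - 1L) %% np)
  ar_class_models(labels = habitat_classes[seq_len(n_classes)],
                  mu = -18 - 6 * substrate,
                  slope = -0.05 - 0.10 * substrate,
                  shape = 8, noise_sd = 5)
}

#' Evaluate a class angular-response law (noiseless)
#' @param models a [ar_class_models()] table.
#' @param class_id integer row index into `models` (vectorised).
#' @param theta incidence angle(s), degrees, unsigned.
#' @return level in dB.
#' @export
ar_model_level <- function(models, class_id, theta) {
  mu <- models$mu[class_id]; sl <- models$slope[class_id]
  sh <- models$shape[class_id]
  lev <- mu + sl * (theta - 40)
  rise <- ifelse(theta < 25, sh * ((25 - theta) / 25)^2, 0)
  lev + rise
}

#' Simulation configuration
#'
#' Defaults state a 500 m x 500 m world at 2.5 m cells (200 x 200), depths
#' from about 25 m sloping to 40 m, survey lines 40 m apart running east-west,
#' 121 beams per ping spanning +-60 degrees (one-degree steps) and one ping
#' per cell along track.
#'
#' @param extent side length of the square study area, metres.
#' @param cell_size grid resolution, metres.
#' @param n_classes number of habitat classes (<= 7).
#' @param base_depth depth at the north-west corner, metres (positive down).
#' @param trend_x,trend_y linear depth trend, metres per metre (x eastward,
#'   y southward from the top edge).
#' @param n_bumps,bump_amp,bump_scale count, amplitude (m) and length scale
#'   (m) of smooth Gaussian seafloor bumps.
#' @param depth_min,depth_max clamp range for depths, metres.
#' @param n_depth_bands depth bands used to condition the habitat map.
#' @param patch_scale habitat patch length scale, metres.
#' @param depth_condition condition habitat classes on depth bands?
#' @param line_gain_sd standard deviation (dB) of a per-survey-line gain
#'   offset, emulating the residual along-track calibration artefacts real
#'   mosaics retain after statistical compensation (a per-line constant passes
#'   through the sliding-window normalization unchanged, while per-segment
#'   angular-response curves pool lines and average it out).
#' @param line_spacing survey line separation, metres.
#' @param ping_spacing along-track ping separation, metres.
#' @param beams_per_ping beams per ping (odd keeps a nadir beam).
#' @param angle_span half-swath steering angle, degrees (must cover >= 50).
#' @param seed integer RNG seed; everything downstream is deterministic in it.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(extent = 500, cell_size = 2.5, n_classes = 4,
                       base_depth = 25, trend_x = 0.03, trend_y = 0,
                       n_bumps = 6, bump_amp = 3, bump_scale = 80,
                       depth_min = 11, depth_max = 80,
                       n_depth_bands = 2, patch_scale = 60,
                       depth_condition = TRUE,
                       line_gain_sd = 2, line_spacing = 40, ping_spacing = 2.5,
                       beams_per_ping = 121, angle_span = 60,
                       seed = 1L) {
  if (angle_span < 50)
    stop("angle_span must cover at least 0-50 degrees (feature band is 30-50)")
  if (extent <= 0 || cell_size <= 0 || extent < cell_size)
    stop("invalid extent/cell_size")
  if (n_classes < 1 || n_classes > length(habitat_classes))
    stop("n_classes must be between 1 and 7")
  if (patch_scale < cell_size)
    stop("patch_scale smaller than one cell")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "SimConfig"
  cfg
}

.grid_dims <- function(cfg) {
  n <- as.integer(round(cfg$extent / cfg$cell_size))
  c(rows = n, cols = n)
}

#' Generate a synthetic bathymetry surface
#'
#' Depth = base + linear trend + sum of Gaussian bumps, clamped to
#' `[depth_min, depth_max]`. Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return `RasterGrid` of depths (metres, positive down), origin (0, extent).
#' @export
gen_bathymetry <- function(cfg) {
  d <- .grid_dims(cfg)
  g0 <- raster_grid(matrix(0, d["rows"], d["cols"]), origin_x = 0,
                    origin_y = cfg$extent, cell_size = cfg$cell_size,
                    crs_tag = "synthetic-local-metres")
  cc <- cell_centre(g0, row(g0$values), col(g0$values))
  x <- matrix(cc$x, d["rows"], d["cols"])
  ysouth <- cfg$extent - matrix(cc$y, d["rows"], d["cols"])
  depth <- cfg$base_depth + cfg$trend_x * x + cfg$trend_y * ysouth
  if (cfg$n_bumps > 0 && cfg$bump_amp > 0) {
    set.seed(cfg$seed)
    cx <- runif(cfg$n_bumps, 0, cfg$extent)
    cy <- runif(cfg$n_bumps, 0, cfg$extent)
    amp <- runif(cfg$n_bumps, -cfg$bump_amp, cfg$bump_amp)
    y <- cfg$extent - ysouth
    for (k in seq_len(cfg$n_bumps)) {
      r2 <- (x - cx[k])^2 + (y - cy[k])^2
      depth <- depth + amp[k] * exp(-r2 / (2 * cfg$bump_scale^2))
    }
  }
  depth <- pmin(pmax(depth, cfg$depth_min), cfg$depth_max)
  with_values(g0, depth)
}

# separable Gaussian smoothing with reflective padding
.smooth_gauss <- function(m, sd_cells) {
  if (sd_cells <= 0) return(m)
  reflect_pad <- function(v, h) c(v[h:1], v, v[length(v):(length(v) - h + 1)])
  conv1 <- function(v) {
    # cap the kernel so reflective padding stays within the vector
    h <- min(max(1L, ceiling(3 * sd_cells)), length(v) - 1L)
    k <- stats::dnorm(seq(-h, h), sd = sd_cells)
    k <- k / sum(k)
    p <- reflect_pad(v, h)
    out <- stats::filter(p, k, sides = 2)
    as.numeric(out[(h + 1):(h + length(v))])
  }
  m2 <- apply(m, 2L, conv1)
  t(apply(m2, 1L, conv1))
}

#' Generate a synthetic habitat map
#'
#' Habitat classes are laid out as depth bands (quantile cuts of the
#' bathymetry, `cfg$n_depth_bands`) crossed with patch types from a smoothed
#' Gaussian random field thresholded at quantiles, so that class is driven by
#' depth *and* by within-band patchiness -- neither bathymetry nor backscatter
#' alone fully determines it. With `depth_condition = FALSE` only the field is
#' used.
#'
#' @param cfg a [sim_config()].
#' @param bathymetry co-registered depth grid from [gen_bathymetry()].
#' @return `RasterGrid` of integer class ids (1..n_classes) with a `labels`
#'   field mapping ids to class labels.
#' @export
gen_habitat_map <- function(cfg, bathymetry) {
  d <- .grid_dims(cfg)
  stopifnot(all(dim(bathymetry$values) == d))
  n <- cfg$n_classes
  if (n == 1L) {
    g <- with_values(bathymetry, matrix(1, d["rows"], d["cols"]))
    g$labels <- habitat_classes[1]
    return(g)
  }
  set.seed(cfg$seed + 1L)
  noise <- matrix(rnorm(prod(d)), d["rows"], d["cols"])
  field <- .smooth_gauss(noise, cfg$patch_scale / cfg$cell_size)
  if (cfg$depth_condition && cfg$n_depth_bands > 1L) {
    nb <- min(cfg$n_depth_bands, n)
    np <- ceiling(n / nb)
    qb <- quantile(bathymetry$values, probs = seq_len(nb - 1) / nb, na.rm = TRUE)
    band <- matrix(findInterval(bathymetry$values, qb) + 1L, d["rows"], d["cols"])
    qp <- quantile(field, probs = seq_len(np - 1) / np)
    patch <- matrix(findInterval(field, qp) + 1L, d["rows"], d["cols"])
    cls <- (band - 1L) * np + patch
    cls[cls > n] <- n
  } else {
    qp <- quantile(field, probs = seq_len(n - 1) / n)
    cls <- matrix(findInterval(field, qp) + 1L, d["rows"], d["cols"])
  }
  present <- sort(unique(as.integer(cls)))
  if (!all(seq_len(n) %in% present))
    stop(sprintf("habitat map failed to realise class id(s) %s; enlarge extent or shrink patch_scale",
                 paste(setdiff(seq_len(n), present), collapse = ", ")))
  g <- with_values(bathymetry, cls)
  g$labels <- habitat_classes[seq_len(n)]
  g
}

#' Simulate per-beam backscatter samples over a survey
#'
#' Parallel east-west lines `cfg$line_spacing` apart; per line, pings every
#' `cfg$ping_spacing` metres; per ping, `cfg$beams_per_ping` beams evenly
#' spaced over `[-angle_span, angle_span]`. Each beam's seafloor footprint is
#' placed across-track at `depth * tan(theta)` from the line (flat-seafloor
#' approximation) and receives the habitat class's angular-response level plus
#' Gaussian noise. Angles are stored unsigned.
#'
#' @param cfg a [sim_config()].
#' @param bathymetry,habitat co-registered grids from the generators above.
#' @param models a [ar_class_models()] table, one row per habitat class.
#' @return `data.table` of samples (`line_id, ping_id, beam_id, x, y, depth,
#'   angle, level`); attribute `skipped` counts beams whose footprint fell
#'   outside the raster.
#' @export
simulate_survey <- function(cfg, bathymetry, habitat, models) {
  if (nrow(models) < max(habitat$values, na.rm = TRUE))
    stop("need one ClassARModel row per habitat class")
  line_y <- seq(cfg$line_spacing / 2, cfg$extent - cfg$line_spacing / 2,
                by = cfg$line_spacing)
  ping_x <- seq(cfg$ping_spacing / 2, cfg$extent, by = cfg$ping_spacing)
  theta_signed <- seq(-cfg$angle_span, cfg$angle_span,
                      length.out = cfg$beams_per_ping)
  nl <- length(line_y); np <- length(ping_x); nb <- length(theta_signed)
  dt <- data.table(line_id = rep(seq_len(nl), each = np * nb),
                   ping_id = rep(rep(seq_len(np), each = nb), times = nl),
                   beam_id = rep(seq_len(nb), times = nl * np))
  dt[, x := ping_x[ping_id]]
  dt[, y0 := line_y[line_id]]
  dt[, theta_s := theta_signed[beam_id]]
  nad <- cell_index(bathymetry, dt$x, dt$y0)
  dt[, depth := bathymetry$values[cbind(nad$row, nad$col)]]
  dt[, y := y0 + depth * tan(theta_s * pi / 180)]
  idx <- cell_index(habitat, dt$x, dt$y)
  inb <- !is.na(idx$row)
  skipped <- sum(!inb)
  dt <- dt[inb]
  dt[, class_id := habitat$values[cbind(idx$row[inb], idx$col[inb])]]
  dt[, angle := abs(theta_s)]
  dt[, level := ar_model_level(models, class_id, angle)]
  set.seed(cfg$seed + 2L)
  if (cfg$line_gain_sd > 0) {
    gains <- rnorm(nl, 0, cfg$line_gain_sd)
    dt[, level := level + gains[line_id]]
  }
  noisy <- models$noise_sd[dt$class_id] > 0
  if (any(noisy)) {
    eps <- rnorm(nrow(dt))
    dt[, level := level + eps * models$noise_sd[class_id]]
  }
  out <- dt[, .(line_id, ping_id, beam_id, x, y, depth, angle, level)]
  if (skipped > 0)
    message(sprintf("simulate_survey: %d beam footprint(s) outside the raster skipped", skipped))
  setattr(out, "skipped", skipped)
  out[]
}

#' Draw ground-truth observation points from the true habitat map
#'
#' Points are placed at cell centres of the true class and split 70/30 into
#' train/test per class (stratified), emulating towed-video reference data.
#'
#' @param habitat class-id grid from [gen_habitat_map()].
#' @param n_per_class points per class.
#' @param seed RNG seed.
#' @param train_frac training fraction (default 0.7).
#' @return `data.table` with `x, y, label, split`.
#' @export
gen_ground_truth <- function(habitat, n_per_class = 150, seed = 1L,
                             train_frac = 0.7) {
  labels <- habitat$labels
  if (is.null(labels)) labels <- habitat_classes[seq_len(max(habitat$values, na.rm = TRUE))]
  set.seed(seed)
  out <- vector("list", length(labels))
  for (k in seq_along(labels)) {
    cells <- which(habitat$values == k)
    if (length(cells) == 0L)
      stop(sprintf("class %s is absent from the habitat map", labels[k]))
    if (length(cells) < n_per_class)
      stop(sprintf("class %s has only %d cells; %d requested",
                   labels[k], length(cells), n_per_class))
    pick <- sample(cells, n_per_class)
    rr <- ((pick - 1L) %% nrow(habitat$values)) + 1L
    cc <- ((pick - 1L) %/% nrow(habitat$values)) + 1L
    ctr <- cell_centre(habitat, rr, cc)
    n_train <- floor(n_per_class * train_frac + 0.5)
    split <- rep("test", n_per_class)
    split[sample(n_per_class, n_train)] <- "train"
    out[[k]] <- data.table(x = ctr$x, y = ctr$y, label = labels[k], split = split)
  }
  rbindlist(out)[]
}
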