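# End-to-end orchestration: from a simulation config (or pre-loaded inputs)
# to the co-registered 18-layer feature stack and evaluated models.

#' Build the full 18-layer feature stack
#'
#' Bathymetry + its six derivatives (complexity, aspect, BPI, slope, maximum
#' curvature, rugosity), the normalized backscatter mosaic + its six
#' derivatives (HSI red/green/blue, GLCM homogeneity/entropy/correlation),
#' and the four angular-response features (mean, slope, skewness, kurtosis)
#' compiled per mosaic segment from pre-normalization samples.
#'
#' @param bathymetry depth `RasterGrid`.
#' @param samples pre-normalization backscatter sample table.
#' @param norm_cfg a [norm_config()].
#' @param seg_cfg a [seg_config()]; the survey-scale default area threshold
#'   (2500 px) is usually too coarse for small scenes -- pass a suitable one.
#' @param bpi_inner,bpi_outer BPI annulus radii in cells.
#' @return list: `stack` (18 layers), `mosaic`, `segments`, `curves`,
#'   `features` (per-segment AR feature table).
#' @export
build_feature_stack <- function(bathymetry, samples,
                                norm_cfg = norm_config(),
                                seg_cfg = seg_config(area_threshold = 250),
                                bpi_inner = 10, bpi_outer = 10) {
  normalized <- angular_normalize(samples, norm_cfg)
  mosaic <- grid_mosaic(normalized, bathymetry)
  segs <- region_grow(mosaic, seg_cfg)
  curves <- compile_ar_curves(samples, segs)
  feats <- ar_features_table(curves)
  ar <- rasterize_features(segs, feats, mosaic)
  m8 <- to_8bit(mosaic)
  glcm <- glcm_features(m8)
  hsi <- hsi_rgb(mosaic)
  stack <- stack_layers(
    bathymetry = bathymetry,
    complexity = complexity(bathymetry),
    aspect = aspect_raster(bathymetry),
    bpi = bpi(bathymetry, bpi_inner, bpi_outer),
    slope = slope_raster(bathymetry),
    max_curvature = max_curvature(bathymetry),
    rugosity = rugosity(bathymetry),
    mosaic = mosaic,
    hsi_red = hsi$red, hsi_green = hsi$green, hsi_blue = hsi$blue,
    glcm_homogeneity = glcm$homogeneity,
    glcm_entropy = glcm$entropy,
    glcm_correlation = glcm$correlation,
    ar_mean = ar$ar_mean, ar_slope = ar$ar_slope,
    ar_skew = ar$ar_skew, ar_kurt = ar$ar_kurt)
  list(stack = stack, mosaic = mosaic, segments = segs, curves = curves,
       features = feats)
}

#' Names of the angular-response layers in the standard stack
#' @export
ar_layer_names <- c("ar_mean", "ar_slope", "ar_skew", "ar_kurt")

#' Simulate a survey and run the with/without-AR model comparison
#'
#' Generates a synthetic world from `cfg`, builds the 18-layer stack, samples
#' it at the ground-truth points and trains two same-seed forests: one without
#' the angular-response layers (the 14-variable baseline) and one with them
#' (all 18). Returns both model runs plus the importance ranking of the full
#' model.
#'
#' @param cfg a [sim_config()]; all randomness derives from `cfg$seed`.
#' @param n_per_class ground-truth points per class.
#' @param models class AR models (default [default_ar_models()]).
#' @param seg_cfg segmentation settings for the scene scale.
#' @return list: `world` (bathymetry, habitat, samples, truth), `layers`
#'   (the [build_feature_stack()] result), `run_without_ar`, `run_with_ar`,
#'   `importance` (full-model ranking).
#' @export
run_recovery_experiment <- function(cfg = sim_config(),
                                    n_per_class = 150,
                                    models = default_ar_models(cfg$n_classes),
                                    seg_cfg = seg_config(area_threshold = 250)) {
  bathy <- gen_bathymetry(cfg)
  habitat <- gen_habitat_map(cfg, bathy)
  samples <- simulate_survey(cfg, bathy, habitat, models)
  truth <- gen_ground_truth(habitat, n_per_class, seed = cfg$seed + 3L)
  layers <- build_feature_stack(bathy, samples, seg_cfg = seg_cfg)
  ft <- sample_stack(layers$stack, truth$x, truth$y)
  ok <- ft$complete
  ft <- ft[, layers$stack$names]
  rf_cfg <- rf_config(seed = cfg$seed)
  no_ar <- setdiff(layers$stack$names, ar_layer_names)
  run1 <- run_model(ft[ok, ], truth$label[ok], truth$split[ok], no_ar, rf_cfg)
  run2 <- run_model(ft[ok, ], truth$label[ok], truth$split[ok],
                    layers$stack$names, rf_cfg)
  list(world = list(bathymetry = bathy, habitat = habitat,
                    samples = samples, truth = truth),
       layers = layers,
       run_without_ar = run1, run_with_ar = run2,
       importance = run2$fit$importance)
}
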