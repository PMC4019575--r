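test_that("compiled curves reproduce a noiseless linear law bin-by-bin", {
  w <- noiseless_world(mu = -30, slope = 0.5)
  segs <- segments_from_labels(w$habitat)
  curves <- compile_ar_curves(w$samples, segs)
  expect_length(curves, 1L)
  cu <- curves[[1]]
  expect_equal(cu$mean_dB[cu$bin_centres == 40], -30, tolerance = 1e-12)
  expect_equal(cu$mean_dB[cu$bin_centres == 50], -25, tolerance = 1e-12)
})

test_that("per-segment curves match each generating class model (simulator oracle)", {
  cfg <- sim_config(extent = 200, n_classes = 2, patch_scale = 50,
                    depth_condition = FALSE, line_gain_sd = 0, seed = 8)
  b <- gen_bathymetry(cfg)
  h <- gen_habitat_map(cfg, b)
  models <- ar_class_models(c("MB", "INV"), mu = c(-22, -34),
                            slope = c(-0.1, -0.3), shape = 5, noise_sd = 0)
  s <- suppressMessages(simulate_survey(cfg, b, h, models))
  segs <- segments_from_labels(h)
  curves <- compile_ar_curves(s, segs)
  lab <- segs$label_raster$values
  for (cu in curves) {
    cid <- unique(h$values[lab == cu$segment_id])
    expect_length(cid, 1L)
    expect_equal(cu$mean_dB, ar_model_level(models, cid, cu$bin_centres),
                 tolerance = 1e-9)
  }
})

test_that("every sample is assigned to exactly one segment via cell membership", {
  w <- noiseless_world()
  segs <- segments_from_labels(w$habitat)
  curves <- compile_ar_curves(w$samples, segs)
  expect_equal(sum(vapply(curves, function(cu) sum(cu$counts), 0)) +
                 attr(curves, "outside"), nrow(w$samples))
})

test_that("ar_features matches closed forms on the symmetric linear curve", {
  th <- 30:50
  cu <- structure(list(segment_id = 1L, bin_centres = th,
                       mean_dB = -30 + 0.5 * (th - 40),
                       counts = rep(10L, 21)), class = "ARCurve")
  f <- ar_features(cu)
  expect_equal(f$ar_mean, -30, tolerance = 1e-12)
  expect_equal(f$ar_slope, 0.5, tolerance = 1e-12)
  expect_lt(abs(f$ar_skewness), 1e-12)
  # kurtosis: brute-force moment oracle over the 21 equally spaced values
  v <- -30 + 0.5 * (th - 40)
  m2 <- mean((v - mean(v))^2); m4 <- mean((v - mean(v))^4)
  expect_equal(f$ar_kurtosis, m4 / m2^2, tolerance = 1e-12)
})

test_that("degenerate and under-populated curves are flagged", {
  flat <- structure(list(segment_id = 2L, bin_centres = 30:50,
                         mean_dB = rep(-25, 21), counts = rep(5L, 21)),
                    class = "ARCurve")
  f <- ar_features(flat)
  expect_true(f$defined)
  expect_equal(f$ar_mean, -25)
  expect_equal(f$ar_slope, 0)
  expect_true(is.na(f$ar_skewness) && is.na(f$ar_kurtosis))

  short <- structure(list(segment_id = 3L, bin_centres = c(31, 35, 42, 48),
                          mean_dB = rep(-20, 4), counts = rep(5L, 4)),
                     class = "ARCurve")
  expect_false(ar_features(short)$defined)
})

test_that("ar_slope is shift-invariant and ar_mean shifts with the curve", {
  set.seed(3)
  th <- 30:50
  v <- -28 - 0.2 * th + rnorm(21, sd = 0.5)
  mk <- function(vals) structure(list(segment_id = 1L, bin_centres = th,
                                      mean_dB = vals, counts = rep(3L, 21)),
                                 class = "ARCurve")
  f0 <- ar_features(mk(v)); f7 <- ar_features(mk(v + 7))
  expect_equal(f7$ar_slope, f0$ar_slope, tolerance = 1e-12)
  expect_equal(f7$ar_mean, f0$ar_mean + 7, tolerance = 1e-12)
  # a curve whose values are symmetric about their mean -> skewness 0
  sym <- -30 + 0.001 * (th - 40)^3
  expect_lt(abs(ar_features(mk(sym))$ar_skewness), 1e-12)
})

test_that("estimated ar_slope is unbiased across Monte-Carlo replicates", {
  set.seed(14)
  th <- 30:50
  R <- 300; true_slope <- -0.25
  est <- vapply(seq_len(R), function(i) {
    cu <- structure(list(segment_id = 1L, bin_centres = th,
                         mean_dB = -30 + true_slope * (th - 40) + rnorm(21, sd = 0.4),
                         counts = rep(8L, 21)), class = "ARCurve")
    ar_features(cu)$ar_slope
  }, 0)
  se <- sd(est) / sqrt(R)
  expect_lt(abs(mean(est) - true_slope), 3 * se)
})

test_that("rasterize_features paints segments piecewise-constant and conserves mass", {
  m <- cbind(matrix(0, 6, 3), matrix(10, 6, 3))
  g <- grid_of(m)
  segs <- region_grow(g, seg_config(1, 1))
  feats <- data.frame(segment_id = 1:2, ar_mean = c(-20, -40),
                      ar_slope = c(0.1, 0.3), ar_skewness = c(0, 0),
                      ar_kurtosis = c(2, NA), defined = TRUE)
  r <- rasterize_features(segs, feats)
  expect_setequal(unique(as.numeric(r$ar_mean$values)), c(-20, -40))
  # histogram mass equals segment pixel counts
  expect_equal(as.integer(table(r$ar_mean$values)), segs$areas[order(segs$means)])
  # zonal mean round trip
  for (sid in 1:2)
    expect_equal(mean(r$ar_mean$values[segs$label_raster$values == sid]),
                 feats$ar_mean[sid])
  # undefined values -> nodata over that segment
  expect_true(all(is.na(r$ar_kurt$values[segs$label_raster$values == 2])))
  expect_warning(compile_ar_curves(data.frame(x = -5, y = -5, angle = 40,
                                              level = -30), segs),
                 "segment")
})
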