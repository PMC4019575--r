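test_that("gen_bathymetry honours analytic configurations and the seed", {
  cfg0 <- sim_config(extent = 50, cell_size = 1, base_depth = 30, trend_x = 0,
                     n_bumps = 0, bump_amp = 0)
  expect_true(all(gen_bathymetry(cfg0)$values == 30))

  cfg1 <- sim_config(extent = 50, cell_size = 2.5, base_depth = 20,
                     trend_x = 0.1, n_bumps = 0)
  b <- gen_bathymetry(cfg1)
  expect_equal(b$values[1, 2] - b$values[1, 1], 0.1 * 2.5, tolerance = 1e-12)
  expect_true(all(b$values >= cfg1$depth_min & b$values <= cfg1$depth_max))

  cfg2 <- sim_config(extent = 100, seed = 1)
  expect_identical(gen_bathymetry(cfg2)$values, gen_bathymetry(cfg2)$values)
})

test_that("gen_habitat_map realises contiguous depth-conditioned classes", {
  cfg <- sim_config(extent = 100, n_classes = 1)
  b <- gen_bathymetry(cfg)
  expect_true(all(gen_habitat_map(cfg, b)$values == 1))

  cfg4 <- sim_config(extent = 200, n_classes = 4, patch_scale = 40, seed = 3)
  b4 <- gen_bathymetry(cfg4)
  h <- gen_habitat_map(cfg4, b4)
  expect_setequal(unique(as.integer(h$values)), 1:4)
  # depth conditioning: classes 1-2 confined to the shallow band
  thr <- quantile(b4$values, 0.5)
  expect_true(all(b4$values[h$values <= 2] <= thr))
  expect_true(all(b4$values[h$values >= 3] >= thr))
  # determinism
  expect_identical(h$values, gen_habitat_map(cfg4, b4)$values)
  # invalid patch scale
  expect_error(sim_config(patch_scale = 1, cell_size = 2.5), "patch_scale")
})

test_that("simulate_survey reproduces the angular law exactly when noiseless", {
  w <- noiseless_world(mu = -30, slope = 0)
  band <- w$samples[w$samples$angle >= 30 & w$samples$angle <= 50, ]
  expect_true(all(abs(band$level - (-30)) < 1e-12))

  w2 <- noiseless_world(mu = -30, slope = 0.5)
  s50 <- w2$samples$level[w2$samples$angle == 50]
  s30 <- w2$samples$level[w2$samples$angle == 30]
  expect_equal(mean(s50) - mean(s30), 10, tolerance = 1e-12)

  # determinism under seed
  w3 <- noiseless_world(seed = 5)
  w4 <- noiseless_world(seed = 5)
  expect_identical(w3$samples$level, w4$samples$level)
})

test_that("noisy sample means obey the CLT bound at a fixed angle", {
  cfg <- sim_config(extent = 150, n_classes = 1, n_bumps = 0, trend_x = 0,
                    line_gain_sd = 0, line_spacing = 5, ping_spacing = 0.5,
                    seed = 11)
  b <- gen_bathymetry(cfg)
  h <- gen_habitat_map(cfg, b)
  models <- ar_class_models("MB", mu = -30, slope = 0, shape = 0, noise_sd = 1)
  s <- suppressMessages(simulate_survey(cfg, b, h, models))
  at40 <- s$level[s$angle == 40]
  expect_gte(length(at40), 1e4)
  at40 <- at40[seq_len(1e4)]
  expect_lt(abs(mean(at40) - (-30)), 3 / sqrt(1e4))
})

test_that("per-line gain offsets shift lines coherently and pass determinism", {
  cfg <- sim_config(extent = 150, n_classes = 1, n_bumps = 0, trend_x = 0,
                    line_gain_sd = 3, seed = 2)
  b <- gen_bathymetry(cfg)
  h <- gen_habitat_map(cfg, b)
  models <- ar_class_models("MB", mu = -30, slope = 0, shape = 0, noise_sd = 0)
  s <- suppressMessages(simulate_survey(cfg, b, h, models))
  per_line <- tapply(s$level[s$angle >= 30 & s$angle <= 50],
                     s$line_id[s$angle >= 30 & s$angle <= 50], mean)
  expect_gt(sd(per_line), 0.5)           # lines genuinely differ
  within <- tapply(s$level[s$angle >= 30 & s$angle <= 50],
                   s$line_id[s$angle >= 30 & s$angle <= 50], sd)
  expect_true(all(within < 1e-12))       # constant within a line (flat AR law)
})

test_that("gen_ground_truth splits 70/30 per class and matches the map", {
  cfg <- sim_config(extent = 150, n_classes = 2, patch_scale = 30, seed = 4)
  b <- gen_bathymetry(cfg)
  h <- gen_habitat_map(cfg, b)
  gt <- gen_ground_truth(h, n_per_class = 10, seed = 1)
  expect_equal(nrow(gt), 20L)
  expect_equal(sum(gt$split == "train"), 14L)
  expect_equal(sum(gt$split == "test"), 6L)
  # labels equal the habitat map value at their cell
  idx <- cell_index(h, gt$x, gt$y)
  expect_equal(gt$label, h$labels[h$values[cbind(idx$row, idx$col)]])
  # different seeds: different point sets, same per-class counts
  gt2 <- gen_ground_truth(h, n_per_class = 10, seed = 2)
  expect_false(identical(gt$x, gt2$x))
  expect_equal(table(gt2$label), table(gt$label))
  # absent class is named
  h1 <- h; h1$labels <- c("MB", "MGI"); h1$values[h1$values == 2] <- 1
  expect_error(gen_ground_truth(h1, 5, 1), "MGI")
})
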