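interior <- function(g, pad = 1) {
  v <- g$values
  v[(1 + pad):(nrow(v) - pad), (1 + pad):(ncol(v) - pad)]
}

test_that("slope and aspect match closed forms on analytic planes", {
  p <- plane_grid(12, gx = 0.1)
  s <- slope_raster(p)
  expect_equal(max(abs(interior(s) - atan(0.1) * 180 / pi)), 0, tolerance = 1e-6)
  # flat plane: slope 0, aspect nodata
  f <- plane_grid(12)
  expect_true(all(interior(slope_raster(f)) == 0))
  expect_true(all(is.na(interior(aspect_raster(f)))))
  # plane dipping due east (depth grows with x) -> aspect 90
  expect_equal(max(abs(interior(aspect_raster(p)) - 90)), 0, tolerance = 1e-6)
  # border windows touch outside -> nodata
  expect_true(all(is.na(s$values[1, ])))
})

test_that("rugosity equals 1 on flat terrain and 1/cos(slope) on ramps", {
  expect_equal(max(abs(interior(rugosity(plane_grid(10))) - 1)), 0,
               tolerance = 1e-9)
  p <- plane_grid(10, gx = 0.2)
  s_deg <- atan(0.2)
  expect_equal(max(abs(interior(rugosity(p)) - 1 / cos(s_deg))), 0,
               tolerance = 1e-6)
  set.seed(5)
  rough <- grid_of(matrix(rnorm(100), 10, 10))
  expect_true(all(interior(rugosity(rough)) >= 1))
})

test_that("curvature and complexity match the quadratic-fit closed forms", {
  p <- plane_grid(12, gx = 0.07, gy = -0.02)
  expect_equal(max(abs(interior(max_curvature(p)))), 0, tolerance = 1e-9)
  # z = 0.01 x^2: fitted x^2 coefficient 0.01, curvature 2a = 0.02
  g0 <- grid_of(matrix(0, 12, 12))
  cc <- cell_centre(g0, row(g0$values), col(g0$values))
  q <- with_values(g0, 0.01 * matrix(cc$x, 12, 12)^2)
  expect_equal(max(abs(interior(max_curvature(q)) - 0.02)), 0, tolerance = 1e-9)
  pp <- max_curvature(q, method = "profile_plan")
  expect_equal(max(abs(interior(pp) - 0.02)), 0, tolerance = 1e-9)
  # complexity of a uniform ramp is 0 (two applications of the 3x3 operator)
  expect_lt(max(abs(interior(complexity(plane_grid(12, gx = 0.3)), pad = 2))),
            1e-9)
})

test_that("BPI vanishes on planes and flags crests", {
  f <- plane_grid(30)
  b <- bpi(f, inner = 3, outer = 3)
  expect_equal(max(abs(interior(b, pad = 4))), 0, tolerance = 1e-9)
  ramp <- plane_grid(30, gx = 0.1, gy = 0.05)
  br <- bpi(ramp, inner = 3, outer = 3)
  expect_equal(max(abs(interior(br, pad = 4))), 0, tolerance = 1e-9)
  # a shoal (locally smaller depth) has positive BPI at its crest
  m <- matrix(50, 30, 30); m[15, 15] <- 45
  bb <- bpi(grid_of(m), inner = 2, outer = 3)
  expect_gt(bb$values[15, 15], 0)
  expect_error(bpi(f, inner = 5, outer = 3), "outer")
})

test_that("high/low-pass filters and the HSI composite behave on edge cases", {
  const <- grid_of(matrix(-25, 15, 15))
  expect_true(all(interior(low_pass(const, 11), pad = 5) == -25))
  expect_true(all(interior(high_pass(const, 3)) == 0))
  rgb <- hsi_rgb(const)
  # constant mosaic: zero high-pass -> zero intensity -> R = G = B constant
  r <- interior(rgb$red, pad = 5); g <- interior(rgb$green, pad = 5)
  b <- interior(rgb$blue, pad = 5)
  expect_true(all(r == r[1, 1]) && all(g == g[1, 1]) && all(b == b[1, 1]))
  expect_true(all(r == g) && all(g == b))
  # step edge: 3x3 high-pass support only within 1 cell of the edge
  step <- grid_of(cbind(matrix(0, 12, 6), matrix(10, 12, 6)))
  hp <- high_pass(step, 3)
  inner_hp <- interior(hp)
  away <- inner_hp[, c(1:3, 8:10)] # columns 2-4 and 9-11 of the full grid
  expect_true(all(away == 0))
  near <- inner_hp[, 5:6]
  expect_true(all(near != 0))
})

test_that("GLCM features match hand-enumerated and oracle values", {
  # checkerboard 4x4 of {0, 255}: all horizontal/vertical pairs are (0,255);
  # diagonal pairs all (0,0)/(255,255)
  board <- outer(1:7, 1:7, function(r, c) ((r + c) %% 2) * 255)
  gb <- grid_of(board)
  feats <- glcm_features(gb, window = 7)
  oracle <- glcm_oracle_patch(board)
  expect_equal(feats$homogeneity$values[4, 4], oracle[1], tolerance = 1e-12)
  expect_equal(feats$entropy$values[4, 4], oracle[2], tolerance = 1e-12)
  expect_equal(feats$correlation$values[4, 4], oracle[3], tolerance = 1e-12)
  # hand enumeration: along rows/columns every pair mixes 0 and 255
  # (correlation -1), along diagonals every pair repeats one value
  # (correlation +1); the 4-direction average is 0
  expect_equal(oracle[3], 0, tolerance = 1e-12)

  # constant window
  cg <- grid_of(matrix(7, 9, 9))
  fc <- glcm_features(cg, window = 7)
  expect_equal(fc$homogeneity$values[5, 5], 1)
  expect_equal(fc$entropy$values[5, 5], 0)
  expect_equal(fc$correlation$values[5, 5], 0)

  # bounds hold on random patches
  set.seed(2)
  rg <- grid_of(matrix(sample(0:255, 81, TRUE), 9, 9))
  fr <- glcm_features(rg, window = 7)
  inner_h <- fr$homogeneity$values[4:6, 4:6]
  expect_true(all(inner_h > 0 & inner_h <= 1))
  expect_true(all(fr$entropy$values[4:6, 4:6] >= 0))

  # non-integer input is refused with guidance
  expect_error(glcm_features(grid_of(matrix(runif(81), 9, 9))), "to_8bit")
})

test_that("window operators propagate nodata", {
  m <- matrix(30, 9, 9); m[5, 5] <- NA
  g <- grid_of(m)
  for (op in list(slope_raster, rugosity, max_curvature,
                  function(x) bpi(x, 0, 2))) {
    out <- op(g)
    expect_true(is.na(out$values[5, 5]) || is.na(out$values[4, 4]))
    expect_true(is.na(out$values[4, 5]))
  }
  gi <- glcm_features(g, window = 3)
  expect_true(all(is.na(gi$entropy$values[4:6, 4:6])))
})
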