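# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately written from the defining formulas, independent of
# the package's implementation paths.

grid_of <- function(m, cell = 1, ox = 0, oy = nrow(as.matrix(m)) * cell) {
  raster_grid(as.matrix(m), origin_x = ox, origin_y = oy, cell_size = cell)
}

# bathymetry plane z = gx * x + gy * (southward distance) + base on an n x n
# grid with unit origin conventions matching gen_bathymetry
plane_grid <- function(n, gx = 0, gy = 0, base = 30, cell = 1) {
  g0 <- grid_of(matrix(0, n, n), cell = cell)
  cc <- cell_centre(g0, row(g0$values), col(g0$values))
  x <- matrix(cc$x, n, n)
  ys <- n * cell - matrix(cc$y, n, n)
  with_values(g0, base + gx * x + gy * ys)
}

# a small noiseless single-class survey world
noiseless_world <- function(mu = -30, slope = 0.5, extent = 150, seed = 1) {
  cfg <- sim_config(extent = extent, n_classes = 1, n_bumps = 0, bump_amp = 0,
                    trend_x = 0.02, line_gain_sd = 0, seed = seed)
  bathy <- gen_bathymetry(cfg)
  habitat <- gen_habitat_map(cfg, bathy)
  models <- ar_class_models("MB", mu = mu, slope = slope, shape = 0, noise_sd = 0)
  samples <- suppressMessages(simulate_survey(cfg, bathy, habitat, models))
  list(cfg = cfg, bathy = bathy, habitat = habitat, models = models,
       samples = samples)
}

# ---- independent GLCM oracle: explicit pair enumeration over one patch ----
glcm_oracle_patch <- function(patch) {
  dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  nr <- nrow(patch); nc <- ncol(patch)
  feats <- sapply(dirs, function(d) {
    pairs <- list()
    for (r in 1:nr) for (c in 1:nc) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        pairs[[length(pairs) + 1]] <- c(patch[r, c], patch[r2, c2])
        pairs[[length(pairs) + 1]] <- c(patch[r2, c2], patch[r, c])
      }
    }
    P <- do.call(rbind, pairs)
    tab <- table(P[, 1], P[, 2]) / nrow(P)
    i <- as.numeric(rownames(tab))[row(tab)]
    j <- as.numeric(colnames(tab))[col(tab)]
    p <- as.numeric(tab)
    hom <- sum(p / (1 + (i - j)^2))
    ent <- -sum(ifelse(p > 0, p * log(p), 0))
    mu <- sum(p * i)
    v <- sum(p * (i - mu)^2)
    cor <- if (v > 0) sum(p * (i - mu) * (j - mu)) / v else 0
    c(hom, ent, cor)
  })
  rowMeans(feats)
}

# ---- independent kappa / variance oracle (delta method, theta terms) ----
kappa_oracle <- function(counts) {
  n <- sum(counts)
  ri <- rowSums(counts); cj <- colSums(counts)
  t1 <- sum(diag(counts)) / n
  t2 <- sum(ri * cj) / n^2
  t3 <- sum(diag(counts) * (ri + cj)) / n^2
  t4 <- 0
  k <- nrow(counts)
  for (i in 1:k) for (j in 1:k) t4 <- t4 + counts[i, j] * (ri[j] + cj[i])^2
  t4 <- t4 / n^3
  kap <- (t1 - t2) / (1 - t2)
  va <- (t1 * (1 - t1) / (1 - t2)^2 +
           2 * (1 - t1) * (2 * t1 * t2 - t3) / (1 - t2)^3 +
           (1 - t1)^2 * (t4 - 4 * t2^2) / (1 - t2)^4) / n
  list(kappa = unname(kap), variance = unname(va))
}

random_error_matrix <- function(k, n = 200) {
  counts <- matrix(stats::rpois(k * k, 2), k, k)
  diag(counts) <- diag(counts) + stats::rpois(k, n / k) + 1
  classes <- LETTERS[seq_len(k)]
  dimnames(counts) <- list(predicted = classes, reference = classes)
  structure(list(counts = counts, classes = classes, N = sum(counts)),
            class = "ErrorMatrix")
}

.ring_area_for_tests <- function(r) {
  x <- r[, 1]; y <- r[, 2]; n <- nrow(r)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

# pooled OLS slope of level on angle over a band (independent of lm)
pooled_slope <- function(angle, level, lo = 30, hi = 50) {
  keep <- angle >= lo & angle <= hi
  a <- angle[keep]; v <- level[keep]
  sum((a - mean(a)) * (v - mean(v))) / sum((a - mean(a))^2)
}
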