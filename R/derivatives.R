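# Terrain derivatives of the bathymetry and texture/colour-composite
# derivatives of the backscatter mosaic. All operators are window operations
# on co-registered grids; any window touching nodata (or the image border)
# emits nodata. Bathymetry grids hold depth in metres positive down; operators
# convert to elevation internally where orientation matters (aspect, BPI).

.shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

.horn_gradients <- function(m, cell) {
  nb <- function(dr, dc) .shift_mat(m, dr, dc)
  gx <- ((nb(-1, 1) + 2 * nb(0, 1) + nb(1, 1)) -
           (nb(-1, -1) + 2 * nb(0, -1) + nb(1, -1))) / (8 * cell)
  gy <- ((nb(-1, -1) + 2 * nb(-1, 0) + nb(-1, 1)) -
           (nb(1, -1) + 2 * nb(1, 0) + nb(1, 1))) / (8 * cell)
  list(gx = gx, gy = gy) # gx: east, gy: north (per unit distance)
}

#' Terrain slope (degrees)
#'
#' Horn's 3x3 finite-difference gradient; slope = atan of the gradient
#' magnitude, in degrees.
#' @param bathy depth `RasterGrid` (metres; sign-free for slope).
#' @return `RasterGrid` of slope in degrees.
#' @export
slope_raster <- function(bathy) {
  g <- .horn_gradients(bathy$values, bathy$cell_size)
  with_values(bathy, atan(sqrt(g$gx^2 + g$gy^2)) * 180 / pi)
}

#' Terrain aspect (degrees from north)
#'
#' Azimuth of the steepest descent direction (the deepening direction for
#' depth grids), clockwise from north in `[0, 360)`. Flat cells are nodata.
#' @param bathy depth `RasterGrid`.
#' @param positive_down is the grid depth positive down (default) or
#'   elevation?
#' @return `RasterGrid` of aspect in degrees.
#' @export
aspect_raster <- function(bathy, positive_down = TRUE) {
  g <- .horn_gradients(bathy$values, bathy$cell_size)
  gx <- g$gx; gy <- g$gy
  if (!positive_down) { gx <- -gx; gy <- -gy }
  asp <- (atan2(gx, gy) * 180 / pi) %% 360
  asp[abs(gx) < 1e-12 & abs(gy) < 1e-12] <- NA_real_
  with_values(bathy, asp)
}

#' Rugosity (surface-area / planar-area ratio)
#'
#' Surface area of the 3x3 window from its eight triangulated facets, divided
#' by the planar window area. 1 on a flat plane, `1/cos(slope)` on an inclined
#' plane, always >= 1.
#' @param bathy depth `RasterGrid`.
#' @return `RasterGrid` of the ratio.
#' @export
rugosity <- function(bathy) {
  m <- bathy$values; cs <- bathy$cell_size
  nb <- function(dr, dc) .shift_mat(m, dr, dc)
  tri_area <- function(zA, zB, zC, xB, yB, xC, yC) {
    # P1 at origin; P2 at (xB, yB, zB - zA); P3 at (xC, yC, zC - zA)
    ux <- xB; uy <- yB; uz <- zB - zA
    vx <- xC; vy <- yC; vz <- zC - zA
    nx <- uy * vz - uz * vy
    ny <- uz * vx - ux * vz
    nz <- ux * vy - uy * vx
    0.5 * sqrt(nx^2 + ny^2 + nz^2)
  }
  total <- 0
  for (dr in c(-1L, 0L)) for (dc in c(-1L, 0L)) {
    A <- nb(dr, dc); B <- nb(dr, dc + 1L)
    C <- nb(dr + 1L, dc); D <- nb(dr + 1L, dc + 1L)
    # split quad along A-D diagonal
    total <- total + tri_area(A, B, D, cs, 0, cs, -cs) +
      tri_area(A, D, C, cs, -cs, 0, -cs)
  }
  with_values(bathy, total / (4 * cs^2))
}

# least-squares local quadratic z = ax^2 + by^2 + cxy + dx + ey + f on the
# 3x3 window; returns the six coefficient rasters (NA where window clipped)
.quad_fit <- function(m, cell) {
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  X <- with(offs, {
    x <- dc * cell; y <- -dr * cell
    cbind(x^2, y^2, x * y, x, y, 1)
  })
  W <- solve(crossprod(X), t(X)) # 6 x 9 exact-fit weights
  coefs <- vector("list", 6L)
  for (k in 1:6) coefs[[k]] <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(offs))) {
    s <- .shift_mat(m, offs$dr[i], offs$dc[i])
    for (k in 1:6) coefs[[k]] <- coefs[[k]] + W[k, i] * s
  }
  names(coefs) <- c("a", "b", "c", "d", "e", "f")
  coefs
}

#' Maximum curvature
#'
#' Local quadratic fit on the 3x3 window. `method = "principal"` (default)
#' returns the largest-magnitude principal curvature (max |eigenvalue| of the
#' Hessian, units 1/m); `method = "profile_plan"` returns the larger magnitude
#' of the profile (along-gradient) and plan (across-gradient) second
#' derivatives, 0 where the surface is locally flat.
#' @param bathy depth `RasterGrid`.
#' @param method `"principal"` or `"profile_plan"`.
#' @return `RasterGrid`.
#' @export
max_curvature <- function(bathy, method = c("principal", "profile_plan")) {
  method <- match.arg(method)
  co <- .quad_fit(bathy$values, bathy$cell_size)
  a <- co$a; b <- co$b; cc <- co$c; d <- co$d; e <- co$e
  if (method == "principal") {
    tr <- a + b
    disc <- sqrt(((a - b))^2 + cc^2)
    l1 <- tr + disc; l2 <- tr - disc # eigenvalues of [[2a, c], [c, 2b]]
    out <- pmax(abs(l1), abs(l2))
  } else {
    g2 <- d^2 + e^2
    prof <- ifelse(g2 > 1e-24, (2 * a * d^2 + 2 * cc * d * e + 2 * b * e^2) / g2, 0)
    plan <- ifelse(g2 > 1e-24, (2 * a * e^2 - 2 * cc * d * e + 2 * b * d^2) / g2, 0)
    out <- pmax(abs(prof), abs(plan))
    out[is.na(a)] <- NA_real_
  }
  with_values(bathy, out)
}

#' Terrain complexity (rate of change of slope)
#'
#' The slope operator applied to the slope raster (degrees of slope change per
#' horizontal distance, expressed as a slope angle). Zero on any constant
#' plane or uniform ramp.
#' @param bathy depth `RasterGrid`.
#' @return `RasterGrid`.
#' @export
complexity <- function(bathy) {
  slope_raster(slope_raster(bathy))
}

#' Bathymetric position index
#'
#' Elevation of each cell minus the mean elevation of a surrounding annulus
#' (`inner < r <= outer` in cells; with `inner == outer` the annulus is the
#' ring of cells within half a cell of that radius). Positive on crests and
#' negative in depressions. For depth-positive-down grids the sign is handled
#' internally so crests (shoals) are positive.
#'
#' @param bathy depth `RasterGrid`.
#' @param inner,outer annulus radii in cells (default 10 and 10).
#' @param positive_down is the grid depth positive down?
#' @param scale if `TRUE`, round to integer (the convention of the common
#'   terrain-modelling tool); default keeps natural units (metres).
#' @return `RasterGrid`.
#' @export
bpi <- function(bathy, inner = 10, outer = 10, positive_down = TRUE,
                scale = FALSE) {
  if (outer < inner) stop("outer radius must be >= inner radius")
  span <- ceiling(outer + 0.5)
  offs <- expand.grid(dr = -span:span, dc = -span:span)
  r <- sqrt(offs$dr^2 + offs$dc^2)
  memb <- if (inner == outer) abs(r - outer) <= 0.5 else r > inner & r <= outer
  offs <- offs[memb, ]
  if (nrow(offs) == 0L) stop("annulus contains no cells")
  m <- bathy$values
  s <- 0
  for (i in seq_len(nrow(offs))) s <- s + .shift_mat(m, offs$dr[i], offs$dc[i])
  ann_mean <- s / nrow(offs)
  out <- if (positive_down) ann_mean - m else m - ann_mean
  if (scale) out <- round(out)
  with_values(bathy, out)
}

# mean filter over a w x w window, nodata/border -> NA
.mean_filter <- function(m, w) {
  half <- (w - 1L) %/% 2L
  s <- 0
  for (dr in -half:half) for (dc in -half:half) s <- s + .shift_mat(m, dr, dc)
  s / (w * w)
}

#' Low-pass (mean) filter
#' @param grid `RasterGrid`.
#' @param window odd window size (default 11).
#' @return `RasterGrid`.
#' @export
low_pass <- function(grid, window = 11) {
  with_values(grid, .mean_filter(grid$values, window))
}

#' High-pass filter (value minus local mean)
#' @param grid `RasterGrid`.
#' @param window odd window size (default 3).
#' @return `RasterGrid`.
#' @export
high_pass <- function(grid, window = 3) {
  with_values(grid, grid$values - .mean_filter(grid$values, window))
}

#' HSI colour-composite layers of the mosaic
#'
#' Low- and high-frequency content of the mosaic rendered as an HSI colour
#' composite and converted to Red/Green/Blue layers: the low-pass (11x11)
#' output drives hue (deep blue for low grey levels through red for high), the
#' high-pass (3x3) magnitude drives intensity, and saturation is fixed. The
#' exact band assignment of the original remote-sensing implementation is not
#' published; this mapping is isolated here so it can be swapped.
#'
#' @param mosaic backscatter mosaic `RasterGrid` (dB or 8-bit).
#' @param lp_window,hp_window filter windows (defaults 11 and 3).
#' @param saturation fixed saturation in `[0, 1]`.
#' @return named list of `RasterGrid`s `red`, `green`, `blue`, scaled 0-255.
#' @export
hsi_rgb <- function(mosaic, lp_window = 11, hp_window = 3, saturation = 0.9) {
  lp <- .mean_filter(mosaic$values, lp_window)
  hp <- mosaic$values - .mean_filter(mosaic$values, hp_window)
  rng <- range(lp, na.rm = TRUE)
  lp_n <- if (diff(rng) > 0) (lp - rng[1]) / diff(rng) else lp * 0
  hue <- 240 * (1 - lp_n) # low grey -> blue (240), high -> red (0)
  hp_scale <- quantile(abs(hp), 0.99, na.rm = TRUE, names = FALSE)
  if (!isTRUE(hp_scale > 0)) hp_scale <- 1
  inten <- pmin(abs(hp) / hp_scale, 1)
  H <- hue; S <- saturation; I <- inten
  deg <- pi / 180
  rgb_from <- function(H0) {
    # standard HSI -> RGB sector formulas (H0 in [0, 120))
    x <- I * (1 - S)
    y <- I * (1 + S * cos(H0 * deg) / cos((60 - H0) * deg))
    z <- 3 * I - (x + y)
    list(x = x, y = y, z = z)
  }
  R <- G <- B <- H * NA_real_
  s1 <- !is.na(H) & H < 120
  s2 <- !is.na(H) & H >= 120 & H < 240
  s3 <- !is.na(H) & H >= 240
  v <- rgb_from(ifelse(s1, H, 0)); R[s1] <- v$y[s1]; B[s1] <- v$x[s1]; G[s1] <- v$z[s1]
  v <- rgb_from(ifelse(s2, H - 120, 0)); G[s2] <- v$y[s2]; R[s2] <- v$x[s2]; B[s2] <- v$z[s2]
  v <- rgb_from(ifelse(s3, H - 240, 0)); B[s3] <- v$y[s3]; G[s3] <- v$x[s3]; R[s3] <- v$z[s3]
  clip255 <- function(m) pmin(pmax(m * 255, 0), 255)
  list(red = with_values(mosaic, clip255(R)),
       green = with_values(mosaic, clip255(G)),
       blue = with_values(mosaic, clip255(B)))
}

#' GLCM texture features of the 8-bit mosaic
#'
#' Per-window grey-level co-occurrence matrices in the 0/45/90/135-degree
#' directions at displacement 1, counted symmetrically with the full 0-255
#' grey range (no requantisation); homogeneity, entropy (natural log) and
#' correlation are extracted per direction and averaged. A constant window
#' gives homogeneity 1, entropy 0 and (by the degenerate-variance rule)
#' correlation 0.
#'
#' @param mosaic_8bit integer-valued `RasterGrid` (from [to_8bit()]).
#' @param window odd window size (default 7).
#' @return named list of `RasterGrid`s `homogeneity`, `entropy`,
#'   `correlation`.
#' @export
glcm_features <- function(mosaic_8bit, window = 7) {
  v <- mosaic_8bit$values
  fin <- v[is.finite(v)]
  if (length(fin) && any(fin != round(fin)))
    stop("glcm_features needs integer grey levels; quantise with to_8bit() first")
  iv <- matrix(as.integer(v), nrow(v), ncol(v))
  res <- .glcm_features_cpp(iv, as.integer(window))
  list(homogeneity = with_values(mosaic_8bit, res$homogeneity),
       entropy = with_values(mosaic_8bit, res$entropy),
       correlation = with_values(mosaic_8bit, res$correlation))
}
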