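# Independent numerical oracles used to cross-check the closed-form
# geometry code. These deliberately use a different computational route
# (dense sampling / rasterization) than the implementation.

# Scanline pixel-rasterization moments of a simple polygon: n x n pixel
# grid over the bounding box; per pixel row, the polygon boundary
# crossings give covered x-intervals, and the per-interval pixel sums of
# 1, x and x^2 are closed-form arithmetic series.
raster_moments <- function(poly, n = 4000L) {
  poly <- as.matrix(poly)
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  pad <- 1e-9 + 1e-6 * max(diff(xr), diff(yr))
  xr <- xr + c(-pad, pad); yr <- yr + c(-pad, pad)
  px <- diff(xr) / n; py <- diff(yr) / n
  xc0 <- xr[1L] + px / 2
  area <- sx <- sy <- sxx <- syy <- sxy <- 0
  k <- nrow(poly)
  x1 <- poly[, 1L]; y1 <- poly[, 2L]
  x2 <- x1[c(2:k, 1L)]; y2 <- y1[c(2:k, 1L)]
  for (row in seq_len(n)) {
    yc <- yr[1L] + (row - 0.5) * py
    cross <- (y1 > yc) != (y2 > yc)
    if (!any(cross)) next
    xs <- sort(x1[cross] + (yc - y1[cross]) / (y2[cross] - y1[cross]) *
                 (x2[cross] - x1[cross]))
    for (m in seq(1L, length(xs) - 1L, by = 2L)) {
      i1 <- ceiling((xs[m] - xc0) / px)
      i2 <- floor((xs[m + 1L] - xc0) / px)
      if (i2 < i1) next
      cnt <- i2 - i1 + 1
      sxi <- xc0 * cnt + px * (i1 + i2) * cnt / 2
      sxxi <- sum((xc0 + (i1:i2) * px)^2)
      area <- area + cnt
      sx <- sx + sxi
      sy <- sy + cnt * yc
      sxx <- sxx + sxxi
      syy <- syy + cnt * yc^2
      sxy <- sxy + yc * sxi
    }
  }
  pA <- px * py
  list(area = area * pA, centroid = c(sx / area, sy / area),
       Ixx = syy * pA, Iyy = sxx * pA, Ixy = sxy * pA)
}

# random star-shaped simple polygon around the origin
random_simple_polygon <- function(k = 12L, r_min = 1, r_max = 4) {
  th <- sort(stats::runif(k, 0, 2 * pi))
  r <- stats::runif(k, r_min, r_max)
  cbind(r * cos(th), r * sin(th))
}

# brute-force ray-intersection oracle for circular contours: sample the
# circle boundary densely, compute each boundary point's polar angle as
# seen from the ray origin, and for each requested ray take the farthest
# boundary point whose angle matches within the sampling step
dense_circle_ray_distance <- function(origin, angles, center, radius,
                                      n_dense = 1e5L) {
  phi <- seq(0, 2 * pi, length.out = n_dense + 1L)[-(n_dense + 1L)]
  bx <- center[1L] + radius * cos(phi) - origin[1L]
  by <- center[2L] + radius * sin(phi) - origin[2L]
  ang <- atan2(by, bx)
  dist <- sqrt(bx^2 + by^2)
  tol <- 4 * pi / n_dense * max(1, max(dist) / radius)
  vapply(angles, function(th) {
    d <- abs(atan2(sin(ang - th), cos(ang - th)))
    hit <- d < tol + 2 * pi / n_dense * 5
    if (!any(hit)) 0 else max(dist[hit])
  }, 0)
}
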