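#' Area, centroid and second moments of a simple closed polygon
#'
#' Closed-form Green's-theorem moments of the region bounded by a simple
#' closed polygon. Moments are exact for polygonal boundaries; no
#' quadrature is involved. Input orientation is normalized: the returned
#' area is positive and moments refer to the counterclockwise polygon.
#'
#' @param poly `k x 2` matrix of vertices (closing edge implied; a
#'   repeated last vertex is tolerated and dropped).
#' @param check_simple verify the polygon is non-self-intersecting
#'   (O(k^2) edge-pair test) and raise a geometry error if it is not.
#' @return list with `area`, `centroid` (length 2), and `Ixx`, `Iyy`,
#'   `Ixy` about the **origin** (x: first column, y: second column;
#'   `Ixx = integral of y^2 dA`, `Iyy = integral of x^2 dA`).
#' @export
polygon_moments <- function(poly, check_simple = TRUE) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L) stop("poly must be a k x 2 matrix")
  if (nrow(poly) > 1L && all(poly[1L, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  k <- nrow(poly)
  if (k < 3L) stop("polygon needs at least 3 vertices")
  if (check_simple && !polygon_is_simple(poly))
    stop("geometry error: polygon is self-intersecting")
  x <- poly[, 1L]; y <- poly[, 2L]
  xj <- c(x[-1L], x[1L]); yj <- c(y[-1L], y[1L])
  cr <- x * yj - xj * y
  A <- sum(cr) / 2
  if (abs(A) < .Machine$double.eps * max(1, max(abs(poly))))
    stop("geometry error: polygon has zero area")
  Cx <- sum((x + xj) * cr) / (6 * A)
  Cy <- sum((y + yj) * cr) / (6 * A)
  Iyy <- sum((x^2 + x * xj + xj^2) * cr) / 12
  Ixx <- sum((y^2 + y * yj + yj^2) * cr) / 12
  Ixy <- sum((x * yj + 2 * x * y + 2 * xj * yj + xj * y) * cr) / 24
  if (A < 0) { A <- -A; Ixx <- -Ixx; Iyy <- -Iyy; Ixy <- -Ixy }
  list(area = A, centroid = c(Cx, Cy), Ixx = Ixx, Iyy = Iyy, Ixy = Ixy)
}

# O(k^2) simplicity test, chunked to bound memory; adjacent edges share a
# vertex and are excluded.
polygon_is_simple <- function(poly) {
  k <- nrow(poly)
  p1 <- poly
  p2 <- poly[c(2:k, 1L), , drop = FALSE]
  block <- max(1L, floor(2e6 / k))
  for (start in seq(1L, k, by = block)) {
    ii <- start:min(start + block - 1L, k)
    for (i in ii) {
      jj <- seq_len(k)
      # skip self and the two adjacent edges (wrapping)
      skip <- c(i, i %% k + 1L, (i - 2L) %% k + 1L)
      jj <- jj[-skip]
      if (length(jj) == 0L) next
      if (any(segments_intersect(p1[i, ], p2[i, ],
                                 p1[jj, , drop = FALSE], p2[jj, , drop = FALSE])))
        return(FALSE)
    }
  }
  TRUE
}

# proper intersection of segment (a,b) with segments (c[i,], d[i,])
segments_intersect <- function(a, b, c, d) {
  o1 <- (b[1L] - a[1L]) * (c[, 2L] - a[2L]) - (b[2L] - a[2L]) * (c[, 1L] - a[1L])
  o2 <- (b[1L] - a[1L]) * (d[, 2L] - a[2L]) - (b[2L] - a[2L]) * (d[, 1L] - a[1L])
  o3 <- (d[, 1L] - c[, 1L]) * (a[2L] - c[, 2L]) - (d[, 2L] - c[, 2L]) * (a[1L] - c[, 1L])
  o4 <- (d[, 1L] - c[, 1L]) * (b[2L] - c[, 2L]) - (d[, 2L] - c[, 2L]) * (b[1L] - c[, 1L])
  (o1 * o2 < 0) & (o3 * o4 < 0)
}

#' Signed area of a closed polygon (positive = counterclockwise)
#' @param poly `k x 2` vertex matrix.
#' @return signed area.
#' @export
polygon_signed_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xj <- c(x[-1L], x[1L]); yj <- c(y[-1L], y[1L])
  sum(x * yj - xj * y) / 2
}

# distances t >= 0 at which the ray origin + t*(cos th, sin th) crosses the
# polygon boundary; vectorized over edges
ray_polygon_hits <- function(poly, origin, theta) {
  dx <- cos(theta); dy <- sin(theta)
  x1 <- poly[, 1L] - origin[1L]; y1 <- poly[, 2L] - origin[2L]
  k <- nrow(poly)
  x2 <- x1[c(2:k, 1L)]; y2 <- y1[c(2:k, 1L)]
  ex <- x2 - x1; ey <- y2 - y1
  den <- dx * ey - dy * ex
  ok <- abs(den) > 1e-14
  # solve origin + t d = p1 + s e
  t <- (x1 * ey - y1 * ex) / den
  s <- (x1 * dy - y1 * dx) / den
  # tolerant endpoint handling: a ray grazing a shared vertex may count the
  # hit on both adjacent edges (harmless -- callers take the farthest hit)
  # but must not lose it on both
  tol <- 1e-9
  hit <- ok & t >= -tol & s >= -tol & s <= 1 + tol
  sort(pmax(t[hit], 0))
}

# even-odd point-in-polygon, single point
point_in_polygon <- function(pt, poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  k <- nrow(poly)
  xj <- x[c(2:k, 1L)]; yj <- y[c(2:k, 1L)]
  crosses <- ((y > pt[2L]) != (yj > pt[2L])) &
    (pt[1L] < (xj - x) * (pt[2L] - y) / (yj - y) + x)
  sum(crosses) %% 2L == 1L
}
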