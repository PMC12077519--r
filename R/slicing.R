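#' Intersect a surface with a transverse plane
#'
#' Slices a [tri_surface()] with the plane `x = level` (x being the
#' proximodistal axis of an oriented bone) and chains the triangle
#' crossings into closed contours in the (y, z) plane. Vertices lying
#' exactly on the plane are handled by an infinitesimal symbolic nudge of
#' the plane.
#'
#' @param surface a `tri_surface` expressed in the anatomical frame.
#' @param level plane coordinate along x (mm).
#' @return list of contours, each a `k x 2` matrix of (y, z) points in
#'   counterclockwise order, sorted by decreasing enclosed area.
#' @export
mesh_section <- function(surface, level) {
  v <- surface$vertices
  f <- surface$faces
  d <- v[, 1L] - level
  # symbolic nudge: treat on-plane vertices as epsilon above
  eps <- 1e-12 * max(1, max(abs(v[, 1L])))
  d[d == 0] <- eps
  s <- d > 0
  s1 <- s[f[, 1L]]; s2 <- s[f[, 2L]]; s3 <- s[f[, 3L]]
  crossing <- which((s1 != s2) | (s2 != s3))
  if (length(crossing) == 0L) return(list())
  fc <- f[crossing, , drop = FALSE]

  # per crossing face, find its two crossing edges and intersection points
  edge_pairs <- rbind(cbind(fc[, 1L], fc[, 2L]),
                      cbind(fc[, 2L], fc[, 3L]),
                      cbind(fc[, 3L], fc[, 1L]))
  di <- d[edge_pairs[, 1L]]; dj <- d[edge_pairs[, 2L]]
  cross_edge <- (di > 0) != (dj > 0)
  # canonical edge key (undirected)
  a <- pmin(edge_pairs[, 1L], edge_pairs[, 2L])
  b <- pmax(edge_pairs[, 1L], edge_pairs[, 2L])
  key <- paste(a, b)
  nfc <- nrow(fc)
  face_of <- rep(seq_len(nfc), 3L)
  ce <- which(cross_edge)
  if (length(ce) != 2L * nfc)
    stop("sectioning error: non-manifold crossing at level ", signif(level, 6))
  # interpolate intersection points on crossing edges
  t <- di[ce] / (di[ce] - dj[ce])
  pi1 <- v[edge_pairs[ce, 1L], , drop = FALSE]
  pi2 <- v[edge_pairs[ce, 2L], , drop = FALSE]
  pts <- pi1 + t * (pi2 - pi1)
  ekey <- key[ce]
  uk <- unique(ekey)
  node <- match(ekey, uk)
  # one representative (y, z) point per unique edge node
  first_idx <- match(uk, ekey)
  node_pts <- pts[first_idx, c(2L, 3L), drop = FALSE]

  # each crossing face contributes a segment between its two edge nodes
  fo <- face_of[ce]
  ord <- order(fo)
  n2 <- matrix(node[ord], ncol = 2L, byrow = TRUE)

  # adjacency between nodes; walk loops
  nn <- length(uk)
  adj1 <- rep(NA_integer_, nn); adj2 <- rep(NA_integer_, nn)
  addadj <- function(from, to) {
    if (is.na(adj1[from])) adj1[from] <<- to
    else if (is.na(adj2[from])) adj2[from] <<- to
    else stop("sectioning error: edge shared by >2 crossing faces at level ",
              signif(level, 6))
  }
  for (i in seq_len(nrow(n2))) {
    addadj(n2[i, 1L], n2[i, 2L])
    addadj(n2[i, 2L], n2[i, 1L])
  }
  visited <- logical(nn)
  contours <- list()
  for (start in seq_len(nn)) {
    if (visited[start]) next
    loop <- integer(0)
    cur <- start; prev <- NA_integer_
    repeat {
      visited[cur] <- TRUE
      loop <- c(loop, cur)
      nxt <- if (!identical(adj1[cur], prev) && !is.na(adj1[cur])) adj1[cur] else adj2[cur]
      if (is.na(nxt)) break          # open chain: boundary-touching slice
      if (nxt == start) { contours[[length(contours) + 1L]] <- loop; break }
      prev <- cur; cur <- nxt
      if (visited[cur]) break
    }
  }
  if (length(contours) == 0L) return(list())
  polys <- lapply(contours, function(idx) node_pts[idx, , drop = FALSE])
  # drop slivers, normalize counterclockwise, sort by area
  areas <- vapply(polys, function(p) abs(polygon_signed_area(p)), numeric(1))
  keep <- areas > 1e-10
  polys <- polys[keep]; areas <- areas[keep]
  polys <- lapply(polys, function(p)
    if (polygon_signed_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p)
  polys[order(areas, decreasing = TRUE)]
}

# crop a surface to a <= x <= b, splitting triangles at the planes
clip_surface_slab <- function(surface, a, b) {
  s <- clip_surface_halfspace(surface, a, above = TRUE)
  clip_surface_halfspace(s, b, above = FALSE)
}

clip_surface_halfspace <- function(surface, level, above = TRUE) {
  v <- surface$vertices
  f <- surface$faces
  d <- if (above) v[, 1L] - level else level - v[, 1L]
  eps <- 1e-12 * max(1, max(abs(v[, 1L])))
  d[d == 0] <- eps
  keepv <- d > 0
  din <- keepv[f[, 1L]] + keepv[f[, 2L]] + keepv[f[, 3L]]
  full <- f[din == 3L, , drop = FALSE]
  partial <- which(din == 1L | din == 2L)
  newv <- list(); newf <- list()
  vcount <- nrow(v)
  interp <- function(i, j) {
    t <- d[i] / (d[i] - d[j])
    v[i, ] + t * (v[j, ] - v[i, ])
  }
  rotate3 <- function(x, rot) x[((seq_len(3L) - 1L + rot) %% 3L) + 1L]
  for (fi in partial) {
    tri <- f[fi, ]
    inside <- keepv[tri]
    if (sum(inside) == 1L) {
      # rotate the kept vertex to position 1, pattern (in, out, out)
      tri <- rotate3(tri, which(inside)[1L] - 1L)
      pA <- interp(tri[1L], tri[2L]); pB <- interp(tri[1L], tri[3L])
      newv[[length(newv) + 1L]] <- rbind(pA, pB)
      newf[[length(newf) + 1L]] <- c(tri[1L], vcount + 1L, vcount + 2L)
      vcount <- vcount + 2L
    } else {
      # rotate the dropped vertex to position 3, pattern (in, in, out)
      tri <- rotate3(tri, which(!inside)[1L] %% 3L)
      pA <- interp(tri[2L], tri[3L]); pB <- interp(tri[1L], tri[3L])
      newv[[length(newv) + 1L]] <- rbind(pA, pB)
      newf[[length(newf) + 1L]] <- c(tri[1L], tri[2L], vcount + 1L)
      newf[[length(newf) + 2L]] <- c(tri[1L], vcount + 1L, vcount + 2L)
      vcount <- vcount + 2L
    }
  }
  v2 <- if (length(newv)) rbind(v, do.call(rbind, newv)) else v
  f2 <- if (length(newf)) rbind(full, do.call(rbind, newf)) else full
  if (nrow(f2) == 0L) stop("cropping error: no geometry remains after clipping")
  # drop unreferenced vertices
  used <- sort(unique(as.integer(f2)))
  remap <- integer(nrow(v2)); remap[used] <- seq_along(used)
  tri_surface(v2[used, , drop = FALSE],
              matrix(remap[f2], ncol = 3L), clean = TRUE)
}
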