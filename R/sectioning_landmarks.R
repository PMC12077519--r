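#' Shaft window
#'
#' Fractions of maximum bone length, measured from the proximal end,
#' bounding the diaphyseal shaft used for cartography. The default
#' (0.20, 0.80) excludes both epiphyses.
#'
#' @param start_frac,end_frac fractions in `[0, 1]`, start < end.
#' @return object of class `shaft_window`.
#' @export
shaft_window <- function(start_frac = 0.20, end_frac = 0.80) {
  if (!(start_frac >= 0 && start_frac < end_frac && end_frac <= 1))
    stop("precondition error: need 0 <= start_frac < end_frac <= 1")
  structure(list(start_frac = start_frac, end_frac = end_frac),
            class = "shaft_window")
}

#' Extract the diaphyseal shaft of an oriented bone
#'
#' Crops both surfaces by transverse planes at `start_frac * L` and
#' `end_frac * L` along u, where L is the maximum bone length.
#'
#' @param pair an oriented [bone_pair()].
#' @param window a [shaft_window()].
#' @return object of class `bone_shaft`: the cropped pair plus the
#'   resolved window, shaft length and absolute x range.
#' @export
define_shaft <- function(pair, window = shaft_window()) {
  if (!isTRUE(pair$oriented)) stop("precondition error: pair must be oriented")
  if (!inherits(window, "shaft_window")) window <- do.call(shaft_window, as.list(window))
  L <- max_length(pair)
  x0 <- min(pair$outer$vertices[, 1L])
  a <- x0 + window$start_frac * L
  b <- x0 + window$end_frac * L
  cropped <- pair
  if (window$start_frac > 0 || window$end_frac < 1) {
    cropped$outer <- clip_surface_slab(pair$outer, a, b)
    cropped$inner <- tryCatch(clip_surface_slab(pair$inner, a, b),
                              error = function(e) pair$inner)
  }
  structure(list(pair = cropped, window = window, bone_length = L,
                 shaft_length = (window$end_frac - window$start_frac) * L,
                 x_range = c(a, b)),
            class = "bone_shaft")
}

#' Slice a shaft into equally spaced cross sections
#'
#' Planes are placed at `n_levels` shaft-length fractions spanning
#' `span` (default 97 sections from 2 to 98 percent at 1 percent
#' intervals). Each plane-mesh intersection is resolved to one closed
#' outer contour and at most one inner contour; when several loops
#' appear, the largest-area loop is kept and the others counted.
#'
#' @param shaft a `bone_shaft` from [define_shaft()].
#' @param n_levels number of sections (default 97).
#' @param span level-fraction range (default `c(0.02, 0.98)`).
#' @return list of `cross_section` objects with fields `level_frac`,
#'   `level_x`, `outer_contour`, `inner_contour` (or NULL), `centroid`.
#' @export
extract_sections <- function(shaft, n_levels = 97L, span = c(0.02, 0.98)) {
  stopifnot(inherits(shaft, "bone_shaft"), n_levels >= 1L,
            span[1L] > 0, span[2L] < 1, span[1L] < span[2L])
  levels <- seq(span[1L], span[2L], length.out = n_levels)
  a <- shaft$x_range[1L]; b <- shaft$x_range[2L]
  lapply(levels, function(lev) {
    x <- a + lev * (b - a)
    outs <- mesh_section(shaft$pair$outer, x)
    if (length(outs) == 0L)
      stop("sectioning error: no closed outer contour at level ", signif(lev, 4))
    ins <- mesh_section(shaft$pair$inner, x)
    if (length(ins) > 1L)
      warning("level ", signif(lev, 4), ": ", length(ins),
              " inner loops; keeping the largest")
    mom <- polygon_moments(outs[[1L]], check_simple = FALSE)
    structure(list(level_frac = lev, level_x = x,
                   outer_contour = outs[[1L]],
                   inner_contour = if (length(ins) >= 1L) ins[[1L]] else NULL,
                   centroid = mom$centroid,
                   n_outer_loops = length(outs), n_inner_loops = length(ins)),
              class = "cross_section")
  })
}

#' Place equiangular semi-landmark pairs on a cross section
#'
#' Rays are cast from the area centroid of the outer contour at `k`
#' equiangular directions starting mid-dorsal (+v) and proceeding
#' counterclockwise viewed from distal. The outer landmark is the
#' farthest ray/outer-contour intersection; the inner landmark the
#' farthest ray/inner-contour intersection. When the inner contour is
#' absent (solid section) or not hit, the inner landmark falls back to
#' the centroid (full-radius cortex) and the cell is flagged. Cortical
#' thickness is the distance between the paired landmarks.
#'
#' @param section a `cross_section`.
#' @param k number of rays (default 50).
#' @return object of class `landmarked_section` with `angles`,
#'   `outer_pts`, `inner_pts` (`k x 2`), `thickness`, `flagged`,
#'   `centroid`, `level_frac`.
#' @export
place_landmarks <- function(section, k = 50L) {
  ctr <- section$centroid
  outer_c <- section$outer_contour
  if (!point_in_polygon(ctr, outer_c))
    stop("landmark error: centroid outside outer contour at level ",
         signif(section$level_frac, 4))
  angles <- theta_grid(k)
  outer_pts <- matrix(0, k, 2L)
  inner_pts <- matrix(0, k, 2L)
  flagged <- logical(k)
  inner_c <- section$inner_contour
  for (j in seq_len(k)) {
    th <- angles[j]
    d <- c(cos(th), sin(th))
    t_out <- ray_polygon_hits(outer_c, ctr, th)
    if (length(t_out) == 0L)
      stop("landmark error: ray ", j, " misses the outer contour at level ",
           signif(section$level_frac, 4))
    ro <- max(t_out)
    outer_pts[j, ] <- ctr + ro * d
    ri <- 0
    if (!is.null(inner_c)) {
      t_in <- ray_polygon_hits(inner_c, ctr, th)
      if (length(t_in) > 0L) ri <- max(t_in) else flagged[j] <- TRUE
    } else flagged[j] <- TRUE
    inner_pts[j, ] <- ctr + ri * d
  }
  thickness <- sqrt(rowSums((outer_pts - inner_pts)^2))
  structure(list(angles = angles, outer_pts = outer_pts, inner_pts = inner_pts,
                 thickness = thickness, flagged = flagged, centroid = ctr,
                 level_frac = section$level_frac),
            class = "landmarked_section")
}

#' Assemble landmarked sections into an unrolled thickness map
#'
#' @param sections list of `landmarked_section`s, one per level, ordered
#'   proximal to distal.
#' @param bone_length maximum bone length (mm).
#' @param n_levels,k expected grid size (defaults 97 x 50).
#' @param meta named list of specimen metadata carried on the map.
#' @return object of class `thickness_map`: `values` (`n_levels x k`
#'   matrix, mm), `mask` (TRUE where the cell was flagged), `levels`,
#'   `angles`, `bone_length`, `standardized`, `meta`.
#' @export
build_thickness_map <- function(sections, bone_length, n_levels = 97L, k = 50L,
                                meta = list()) {
  if (length(sections) != n_levels)
    stop("shape error: expected ", n_levels, " sections, got ", length(sections))
  bad <- which(vapply(sections, function(s) length(s$thickness), 0L) != k)
  if (length(bad))
    stop("shape error: section ", bad[1L], " has ",
         length(sections[[bad[1L]]]$thickness), " landmarks, expected ", k)
  values <- do.call(rbind, lapply(sections, `[[`, "thickness"))
  mask <- do.call(rbind, lapply(sections, `[[`, "flagged"))
  structure(list(values = values, mask = mask,
                 levels = vapply(sections, `[[`, 0, "level_frac"),
                 angles = sections[[1L]]$angles,
                 bone_length = bone_length, standardized = FALSE, meta = meta),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map %dx%d, L = %.2f mm, %s, %d flagged cells>\n",
              nrow(x$values), ncol(x$values), x$bone_length,
              if (x$standardized) "standardized" else "mm", sum(x$mask)))
  invisible(x)
}

#' Full cartography of one bone: shaft, sections, landmarks, map
#'
#' Convenience wrapper running [define_shaft()], [extract_sections()],
#' [place_landmarks()] and [build_thickness_map()].
#'
#' @param pair an oriented [bone_pair()] (right-side convention; mirror
#'   left bones first).
#' @param window a [shaft_window()].
#' @param n_levels,k grid size (defaults 97 x 50).
#' @param span level span (default `c(0.02, 0.98)`).
#' @return a `thickness_map`.
#' @export
compute_thickness_map <- function(pair, window = shaft_window(),
                                  n_levels = 97L, k = 50L,
                                  span = c(0.02, 0.98)) {
  shaft <- define_shaft(pair, window)
  sections <- extract_sections(shaft, n_levels = n_levels, span = span)
  lms <- lapply(sections, place_landmarks, k = k)
  build_thickness_map(lms, bone_length = shaft$bone_length,
                      n_levels = n_levels, k = k,
                      meta = list(id = pair$id, label = pair$label,
                                  element = pair$element, digit = pair$digit,
                                  side = pair$side,
                                  window = c(window$start_frac, window$end_frac),
                                  span = span))
}
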