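#' Cross-sectional geometry of a cortical annulus
#'
#' Properties of the region between an outer and an (optional) inner
#' contour: cortical area, combined centroid, second moments about the
#' centroid and the polar second moment of area J = Ixx + Iyy. Moments
#' are closed-form polygon moments (outer minus inner) translated to the
#' cortical-area centroid by the parallel-axis theorem. Axes follow the
#' map convention: x = w (radial), y = v (dorsal) -- contour columns are
#' (v, w), i.e. (y, x).
#'
#' @param outer_contour `k x 2` matrix (v, w) in mm.
#' @param inner_contour `k x 2` matrix or NULL for a solid section.
#' @param thickness optional vector of the 50 ray thicknesses at this
#'   level; its mean is reported as `mean_thickness`.
#' @param level_frac level as a fraction of max bone length (metadata).
#' @param check_simple verify contours are simple polygons.
#' @return object of class `section_geometry`: `level_frac`,
#'   `cortical_area` (mm^2), `centroid`, `Ixx`, `Iyy`, `Ixy` (mm^4,
#'   centroidal), `J` (mm^4), `mean_thickness` (mm or NA).
#' @export
section_J <- function(outer_contour, inner_contour = NULL, thickness = NULL,
                      level_frac = NA_real_, check_simple = TRUE) {
  mo <- polygon_moments(outer_contour, check_simple = check_simple)
  if (!is.null(inner_contour)) {
    mi <- polygon_moments(inner_contour, check_simple = check_simple)
    if (mi$area >= mo$area)
      stop("geometry error: inner contour at least as large as outer")
    if (!point_in_polygon(mi$centroid, outer_contour))
      stop("geometry error: inner contour not contained in outer")
    A <- mo$area - mi$area
    cx <- (mo$area * mo$centroid[1L] - mi$area * mi$centroid[1L]) / A
    cy <- (mo$area * mo$centroid[2L] - mi$area * mi$centroid[2L]) / A
    Ixx_o <- mo$Ixx - mi$Ixx
    Iyy_o <- mo$Iyy - mi$Iyy
    Ixy_o <- mo$Ixy - mi$Ixy
  } else {
    A <- mo$area
    cx <- mo$centroid[1L]; cy <- mo$centroid[2L]
    Ixx_o <- mo$Ixx; Iyy_o <- mo$Iyy; Ixy_o <- mo$Ixy
  }
  # parallel axis: origin moments -> centroidal moments
  Ixx <- Ixx_o - A * cy^2
  Iyy <- Iyy_o - A * cx^2
  Ixy <- Ixy_o - A * cx * cy
  structure(list(level_frac = level_frac, cortical_area = A,
                 centroid = c(cx, cy), Ixx = Ixx, Iyy = Iyy, Ixy = Ixy,
                 J = Ixx + Iyy,
                 mean_thickness = if (is.null(thickness)) NA_real_ else mean(thickness)),
            class = "section_geometry")
}

#' Cross-sectional properties at fractions of bone length
#'
#' Slices the whole (uncropped) bone at the requested fractions of
#' maximum bone length from the proximal end -- by default 35, 50 and 65
#' percent -- and computes [section_J()] plus the mean of the 50 ray
#' thicknesses at each level. Note these levels refer to bone length,
#' not shaft length as in the thickness-map grid.
#'
#' @param pair an oriented [bone_pair()].
#' @param levels fractions of max bone length in (0, 1).
#' @param k number of thickness rays (default 50).
#' @return list of `section_geometry` objects.
#' @export
J_at_levels <- function(pair, levels = c(0.35, 0.50, 0.65), k = 50L) {
  if (!isTRUE(pair$oriented)) stop("precondition error: pair must be oriented")
  if (any(levels <= 0 | levels >= 1)) stop("levels must lie strictly in (0, 1)")
  x0 <- min(pair$outer$vertices[, 1L])
  L <- max_length(pair)
  lapply(levels, function(lev) {
    x <- x0 + lev * L
    outs <- mesh_section(pair$outer, x)
    if (length(outs) == 0L)
      stop("sectioning error: no outer contour at bone-length fraction ", lev)
    ins <- mesh_section(pair$inner, x)
    mom <- polygon_moments(outs[[1L]], check_simple = FALSE)
    cs <- structure(list(level_frac = lev, level_x = x,
                         outer_contour = outs[[1L]],
                         inner_contour = if (length(ins)) ins[[1L]] else NULL,
                         centroid = mom$centroid),
                    class = "cross_section")
    lm <- place_landmarks(cs, k = k)
    section_J(cs$outer_contour, cs$inner_contour, thickness = lm$thickness,
              level_frac = lev, check_simple = FALSE)
  })
}

#' Length-standardize a polar second moment of area
#'
#' Returns `J / bone_length^exponent`. The default exponent 4 makes the
#' quantity dimensionless (J has units of length^4); the exponent is a
#' first-class argument and is echoed in the result.
#'
#' @param geom a `section_geometry` (or a bare J value).
#' @param bone_length maximum bone length (mm), > 0.
#' @param exponent standardization exponent (default 4).
#' @return list with `J_std`, `exponent`, `level_frac`.
#' @export
standardize_J <- function(geom, bone_length, exponent = 4) {
  if (!is.finite(bone_length) || bone_length <= 0)
    stop("bone_length must be positive")
  J <- if (inherits(geom, "section_geometry")) geom$J else as.numeric(geom)
  list(J_std = J / bone_length^exponent, exponent = exponent,
       level_frac = if (inherits(geom, "section_geometry")) geom$level_frac else NA_real_)
}

#' Longitudinal curvature via the included angle
#'
#' Projects the shaft section centroids onto the sagittal (u-v) plane,
#' fits a circle (Kasa algebraic fit refined by one Gauss-Newton pass)
#' and reports the angle subtended at the fitted center by the arc
#' between the proximal-most and distal-most centroids. Bones whose
#' fitted radius exceeds `straight_ratio` times the shaft length are
#' reported as straight (0 degrees).
#'
#' @param pair an oriented [bone_pair()].
#' @param window [shaft_window()] over which centroids are collected.
#' @param n_levels number of section centroids (>= 10).
#' @param straight_ratio straightness threshold on radius/shaft length.
#' @return object of class `curvature_result`: `included_angle`
#'   (degrees), `fit_radius` (mm), `fit_rmse` (mm).
#' @export
included_angle <- function(pair, window = shaft_window(), n_levels = 33L,
                           straight_ratio = 50) {
  if (n_levels < 10L) stop("need at least 10 section centroids")
  shaft <- define_shaft(pair, window)
  secs <- extract_sections(shaft, n_levels = n_levels, span = c(0.02, 0.98))
  pts <- cbind(vapply(secs, `[[`, 0, "level_x"),
               vapply(secs, function(s) s$centroid[1L], 0))
  fit <- .fit_circle(pts)
  if (!is.finite(fit$R) || fit$R > straight_ratio * shaft$shaft_length) {
    ang <- 0
  } else {
    # the centroids cover only the shaft window; extend the fitted arc to
    # the full proximodistal extent of the bone before taking the angle
    xr <- range(pair$outer$vertices[, 1L])
    ends <- vapply(xr, function(x) {
      dx <- x - fit$cx
      dy2 <- fit$R^2 - dx^2
      y <- if (dy2 > 0) {
        branch <- sign(mean(pts[, 2L]) - fit$cy)
        fit$cy + branch * sqrt(dy2)
      } else fit$cy
      atan2(y - fit$cy, dx)
    }, 0)
    ang <- abs(.wrap_angle(ends[2L] - ends[1L])) * 180 / pi
  }
  structure(list(included_angle = ang, fit_radius = fit$R, fit_rmse = fit$rmse),
            class = "curvature_result")
}

# Kasa algebraic circle fit + one Gauss-Newton refinement
.fit_circle <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  sol <- tryCatch(unname(qr.solve(A, b)), error = function(e) NULL)
  if (is.null(sol)) return(list(cx = NA, cy = NA, R = Inf, rmse = NA))
  cx <- -sol[1L] / 2; cy <- -sol[2L] / 2
  R2 <- cx^2 + cy^2 - sol[3L]
  if (R2 <= 0) return(list(cx = cx, cy = cy, R = Inf, rmse = NA))
  R <- sqrt(R2)
  # one geometric Gauss-Newton step
  for (it in 1L) {
    dx <- x - cx; dy <- y - cy
    rho <- sqrt(dx^2 + dy^2)
    r <- rho - R
    Jm <- cbind(-dx / rho, -dy / rho, rep(-1, length(x)))
    step <- tryCatch(unname(qr.solve(Jm, -r)), error = function(e) c(0, 0, 0))
    cx <- cx + step[1L]; cy <- cy + step[2L]; R <- R + step[3L]
  }
  dx <- x - cx; dy <- y - cy
  rmse <- sqrt(mean((sqrt(dx^2 + dy^2) - R)^2))
  list(cx = cx, cy = cy, R = R, rmse = rmse)
}

#' Mechanics summary table for a set of bones
#'
#' One row per specimen and level: area, centroidal moments, J, length
#' standardized J, mean ray thickness (raw and standardized) and the
#' bone's included angle.
#'
#' @param pairs list of oriented [bone_pair()]s.
#' @param levels bone-length fractions for [J_at_levels()].
#' @param exponent standardization exponent for J.
#' @param window shaft window for the curvature fit.
#' @return data.frame.
#' @export
mechanics_table <- function(pairs, levels = c(0.35, 0.50, 0.65), exponent = 4,
                            window = shaft_window()) {
  rows <- lapply(pairs, function(p) {
    L <- max_length(p)
    geoms <- J_at_levels(p, levels = levels)
    ang <- included_angle(p, window = window)
    do.call(rbind, lapply(geoms, function(g) {
      data.frame(id = p$id, group = p$label, element = p$element,
                 digit = p$digit, side = p$side, bone_length = L,
                 level_frac = g$level_frac, cortical_area = g$cortical_area,
                 Ixx = g$Ixx, Iyy = g$Iyy, Ixy = g$Ixy, J = g$J,
                 J_std = standardize_J(g, L, exponent)$J_std,
                 J_std_exponent = exponent,
                 mean_thickness = g$mean_thickness,
                 mean_thickness_std = g$mean_thickness / L,
                 included_angle = ang$included_angle,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
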