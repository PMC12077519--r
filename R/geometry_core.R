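#' Anatomical coordinate frame
#'
#' Right-handed orthonormal frame for an oriented phalanx: `u` points
#' proximal-to-distal, `v` toward the dorsal surface, `w = u x v` toward
#' the radial side of a right-hand bone. The origin sits at the proximal
#' extreme of the outer surface.
#'
#' @param origin length-3 point (mm), in the source coordinates.
#' @param u,v,w length-3 unit vectors.
#' @return object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin = c(0, 0, 0),
                             u = c(1, 0, 0), v = c(0, 1, 0), w = c(0, 0, 1)) {
  R <- cbind(u, v, w)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("frame axes must be orthonormal")
  if (max(abs(cross3(u, v) - w)) > 1e-6)
    stop("frame must be right-handed (u x v = w)")
  structure(list(origin = as.numeric(origin), u = as.numeric(u),
                 v = as.numeric(v), w = as.numeric(w)),
            class = "anatomical_frame")
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Paired outer/inner bone surfaces
#'
#' The specimen unit of all analyses: an outer (periosteal) and inner
#' (endosteal) surface of one phalangeal diaphysis, plus specimen
#' metadata. Once oriented (see [orient_anatomical()]) the vertex
#' coordinates are expressed in the anatomical frame: column 1 = u
#' (proximodistal, 0 at the proximal extreme), column 2 = v (dorsal),
#' column 3 = w (radial, right-hand convention).
#'
#' @param outer,inner [tri_surface()] objects.
#' @param side `"left"`, `"right"` or `NA`.
#' @param label group/taxon tag.
#' @param element `"PP"` (proximal) or `"IP"` (intermediate).
#' @param digit ray number 1-5 or `NA`.
#' @param frame an [anatomical_frame()] or `NULL` (unoriented).
#' @param oriented logical; whether coordinates are already anatomical.
#' @param id specimen identifier.
#' @return object of class `bone_pair`.
#' @export
bone_pair <- function(outer, inner, side = NA_character_, label = NA_character_,
                      element = NA_character_, digit = NA_integer_,
                      frame = NULL, oriented = FALSE, id = NA_character_) {
  stopifnot(inherits(outer, "tri_surface"), inherits(inner, "tri_surface"))
  if (!is.na(side) && !side %in% c("left", "right"))
    stop("side must be 'left', 'right' or NA")
  if (!is.na(element) && !element %in% c("PP", "IP"))
    stop("element must be 'PP' or 'IP'")
  structure(list(outer = outer, inner = inner, side = side, label = label,
                 element = element, digit = as.integer(digit), frame = frame,
                 oriented = isTRUE(oriented), id = id),
            class = "bone_pair")
}

#' @export
print.bone_pair <- function(x, ...) {
  cat(sprintf("<bone_pair %s: %s %s digit %s, side %s, %s>\n",
              x$id, x$label, x$element, x$digit, x$side,
              if (x$oriented) "oriented" else "unoriented"))
  invisible(x)
}

#' Orient a bone pair into the canonical anatomical frame
#'
#' Finds the dominant elongation axis of the outer vertex scatter and
#' assigns it to u, signed so that the broader metaphyseal end (larger
#' mean cross-sectional area over the proximal vs distal deciles) lies
#' proximal. The dorsal axis v is the second principal axis, signed so
#' that shaft section centroids deviate palmarly (toward -v) from the
#' proximodistal chord -- phalanges bow palmarly. Both conventions can be
#' overridden with `hints` (approximate direction vectors `u` and/or `v`
#' in the input coordinates). Output geometry is re-expressed in the new
#' frame with the origin at the proximal extreme.
#'
#' @param pair a [bone_pair()].
#' @param hints optional list with elements `u` and/or `v`.
#' @param elongation_threshold minimum ratio of first to second principal
#'   standard deviation below which orientation fails (default 1.2).
#' @return oriented `bone_pair` (vertices in anatomical coordinates,
#'   `frame` recording the recovered axes in input coordinates).
#' @export
orient_anatomical <- function(pair, hints = NULL, elongation_threshold = 1.2) {
  X <- pair$outer$vertices
  if (nrow(X) < 4L) stop("need at least 4 outer vertices")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  eg <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  sds <- sqrt(pmax(eg$values, 0))
  if (sds[2L] <= 0 || sds[1L] / sds[2L] < elongation_threshold)
    stop("orientation failure: vertex scatter too isotropic (elongation ratio ",
         signif(sds[1L] / max(sds[2L], 1e-300), 3), " < ", elongation_threshold, ")")
  u <- eg$vectors[, 1L]
  if (!is.null(hints$u)) {
    if (sum(u * hints$u) < 0) u <- -u
  } else {
    xu <- as.numeric(Xc %*% u)
    if (!.broader_at_low_end(pair$outer, ctr, u, xu)) u <- -u
  }
  if (!is.null(hints$v)) {
    hv <- hints$v - sum(hints$v * u) * u
    if (sqrt(sum(hv^2)) < 1e-8) stop("v hint is parallel to the long axis")
    v <- hv / sqrt(sum(hv^2))
  } else {
    # the dorsopalmar axis is the cross-section direction carrying the
    # palmar bow of the shaft; for straight bones fall back to the flatter
    # (smaller-spread) section axis -- phalangeal sections are wider
    # radioulnarly than dorsopalmarly
    cands <- list(eg$vectors[, 2L], eg$vectors[, 3L])
    devs <- vapply(cands, function(vv) .centroid_sagittal_deviation(Xc, u, vv), 0)
    vars <- vapply(cands, function(vv) stats::var(as.numeric(Xc %*% vv)), 0)
    thr <- 1e-3 * sqrt(max(vars))
    pick <- if (max(abs(devs)) > thr) which.max(abs(devs)) else which.min(vars)
    v0 <- cands[[pick]]
    if (abs(devs[pick]) > thr) {
      # centroids bow palmarly: dorsal is opposite the deviation
      v <- if (devs[pick] > 0) -v0 else v0
    } else {
      # no palmar bow: deterministic sign convention
      v <- if (v0[which.max(abs(v0))] < 0) -v0 else v0
    }
  }
  w <- cross3(u, v)
  R <- cbind(u, v, w)
  q_out <- sweep(pair$outer$vertices, 2L, ctr) %*% R
  q_in <- sweep(pair$inner$vertices, 2L, ctr) %*% R
  x0 <- min(q_out[, 1L])
  q_out[, 1L] <- q_out[, 1L] - x0
  q_in[, 1L] <- q_in[, 1L] - x0
  origin <- ctr + x0 * u
  out <- pair
  out$outer <- structure(list(vertices = q_out, faces = pair$outer$faces),
                         class = "tri_surface")
  out$inner <- structure(list(vertices = q_in, faces = pair$inner$faces),
                         class = "tri_surface")
  out$frame <- anatomical_frame(origin, u, v, w)
  out$oriented <- TRUE
  out
}

# compare mean outer section area over the two end deciles by slicing;
# TRUE if the low-x end is broader (i.e. already proximal)
.broader_at_low_end <- function(surf, ctr, u, xu) {
  rng <- range(xu)
  ext <- diff(rng)
  # provisional frame for slicing
  v0 <- if (abs(u[1L]) < 0.9) cross3(u, c(1, 0, 0)) else cross3(u, c(0, 1, 0))
  v0 <- v0 / sqrt(sum(v0^2))
  w0 <- cross3(u, v0)
  prov <- structure(list(
    vertices = sweep(surf$vertices, 2L, ctr) %*% cbind(u, v0, w0),
    faces = surf$faces), class = "tri_surface")
  lev_lo <- rng[1L] + c(0.03, 0.06, 0.09) * ext
  lev_hi <- rng[2L] - c(0.03, 0.06, 0.09) * ext
  area_at <- function(lev) {
    cs <- tryCatch(mesh_section(prov, lev), error = function(e) list())
    if (length(cs) == 0L) return(NA_real_)
    abs(polygon_signed_area(cs[[1L]]))
  }
  a_lo <- mean(vapply(lev_lo, area_at, numeric(1)), na.rm = TRUE)
  a_hi <- mean(vapply(lev_hi, area_at, numeric(1)), na.rm = TRUE)
  if (is.nan(a_lo) || is.nan(a_hi)) {
    # fallback: radial vertex spread as an area proxy
    lo <- xu <= rng[1L] + 0.1 * ext
    hi <- xu >= rng[2L] - 0.1 * ext
    Xc <- sweep(surf$vertices, 2L, ctr)
    r2 <- rowSums((Xc - xu %o% u)^2)
    a_lo <- mean(r2[lo]); a_hi <- mean(r2[hi])
  }
  a_lo >= a_hi
}

# mean deviation (along candidate v) of per-level vertex centroids from the
# chord joining the two shaft ends; positive = bowing toward +v
.centroid_sagittal_deviation <- function(Xc, u, v) {
  xu <- as.numeric(Xc %*% u)
  yv <- as.numeric(Xc %*% v)
  rng <- range(xu)
  br <- seq(rng[1L], rng[2L], length.out = 21L)
  bin <- cut(xu, br, include.lowest = TRUE, labels = FALSE)
  ym <- tapply(yv, bin, mean)
  xm <- tapply(xu, bin, mean)
  ids <- as.integer(names(ym))
  n <- length(ym)
  if (n < 5L) return(0)
  # chord through the end-bin means; deviation over the middle 60%
  slope <- (ym[n] - ym[1L]) / (xm[n] - xm[1L])
  chord <- ym[1L] + slope * (xm - xm[1L])
  mid <- ids > 4L & ids < 18L
  mean((ym - chord)[mid])
}

#' Maximum phalangeal length
#'
#' Maximum proximodistal extent of the outer surface: the distance along
#' u from the proximal-most point of the base to the distal-most point of
#' the trochlea.
#'
#' @param pair an oriented [bone_pair()].
#' @return length in mm.
#' @export
max_length <- function(pair) {
  if (!isTRUE(pair$oriented))
    stop("precondition error: pair must be oriented (see orient_anatomical)")
  diff(range(pair$outer$vertices[, 1L]))
}

#' Mirror a left-side bone into the right-side convention
#'
#' Left bones are reflected across the sagittal (u-v) plane so that every
#' specimen shares one angular map convention; right bones pass through
#' unchanged.
#'
#' @param pair a [bone_pair()] with known side.
#' @return right-convention `bone_pair`.
#' @export
mirror_to_right <- function(pair) {
  if (is.na(pair$side))
    stop("side is unknown: assign side = 'left' or 'right' explicitly before mirroring")
  if (pair$side == "right") return(pair)
  refl <- function(s) {
    v <- s$vertices
    v[, 3L] <- -v[, 3L]
    structure(list(vertices = v, faces = s$faces[, c(1L, 3L, 2L), drop = FALSE]),
              class = "tri_surface")
  }
  out <- pair
  out$outer <- refl(pair$outer)
  out$inner <- refl(pair$inner)
  out$side <- "right"
  out
}

#' Check that the inner surface lies inside the outer surface
#'
#' Samples random inner vertices and tests each against the outer section
#' contour at its proximodistal level.
#'
#' @param pair oriented [bone_pair()].
#' @param n number of inner vertices to sample (at least 100).
#' @param seed RNG seed for the sample.
#' @return TRUE invisibly, or an error naming the first offending vertex.
#' @export
check_containment <- function(pair, n = 100L, seed = 1L) {
  if (!isTRUE(pair$oriented)) stop("pair must be oriented")
  vi <- pair$inner$vertices
  xr <- range(pair$outer$vertices[, 1L])
  # keep away from the extreme ends where sections degenerate
  ok_lvl <- vi[, 1L] > xr[1L] + 0.02 * diff(xr) & vi[, 1L] < xr[2L] - 0.02 * diff(xr)
  cand <- which(ok_lvl)
  idx <- withr_seed(seed, sample(cand, min(max(n, 100L), length(cand))))
  for (i in idx) {
    cs <- mesh_section(pair$outer, vi[i, 1L])
    if (length(cs) == 0L) next
    if (!point_in_polygon(vi[i, 2:3], cs[[1L]]))
      stop("inner surface vertex ", i, " lies outside the outer surface at u = ",
           signif(vi[i, 1L], 5))
  }
  invisible(TRUE)
}

# run expr with a local RNG seed, restoring the global state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
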