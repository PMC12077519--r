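#' Triangle surface
#'
#' A minimal triangle-mesh container: an `n x 3` numeric matrix of vertex
#' coordinates in millimetres and an `m x 3` integer matrix of 1-based
#' vertex indices, one row per triangular face.
#'
#' @param vertices numeric matrix, `n x 3`, vertex coordinates (mm).
#' @param faces integer matrix, `m x 3`, 1-based vertex indices.
#' @param clean logical; merge duplicate vertices and drop degenerate
#'   (zero-area) faces on construction.
#' @return An object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, faces, clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix of vertex indices")
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range: faces reference vertices 1..", nrow(vertices))
  s <- structure(list(vertices = vertices, faces = faces), class = "tri_surface")
  if (clean) s <- clean_surface(s) else s
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("<tri_surface: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

n_vertices <- function(s) nrow(s$vertices)
n_faces <- function(s) nrow(s$faces)

#' Merge duplicate vertices and drop degenerate faces
#'
#' Vertices closer than `tol` (exact coordinate duplicates by default) are
#' merged; faces with repeated indices or zero area are removed.
#'
#' @param surface a [tri_surface()].
#' @param tol coordinate rounding tolerance used for duplicate detection.
#' @return cleaned `tri_surface`.
#' @export
clean_surface <- function(surface, tol = 1e-9) {
  v <- surface$vertices
  f <- surface$faces
  key <- apply(round(v / tol) * tol, 1L, paste, collapse = ",")
  first <- !duplicated(key)
  # position of each vertex in the deduplicated vertex list
  remap <- match(key, key[first])
  v2 <- v[first, , drop = FALSE]
  if (nrow(f) > 0L) {
    f2 <- matrix(remap[f], ncol = 3L)
    # repeated-index faces are degenerate by construction
    ok <- f2[, 1L] != f2[, 2L] & f2[, 2L] != f2[, 3L] & f2[, 1L] != f2[, 3L]
    if (any(ok)) {
      a <- v2[f2[ok, 2L], , drop = FALSE] - v2[f2[ok, 1L], , drop = FALSE]
      b <- v2[f2[ok, 3L], , drop = FALSE] - v2[f2[ok, 1L], , drop = FALSE]
      cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
      cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
      cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
      area2 <- sqrt(cx^2 + cy^2 + cz^2)
      keep <- which(ok)[area2 > 1e-14]
    } else keep <- integer(0)
    f2 <- f2[keep, , drop = FALSE]
  } else f2 <- f
  structure(list(vertices = v2, faces = f2), class = "tri_surface")
}

#' Apply a rigid (or affine) transform to a surface
#'
#' @param surface a [tri_surface()].
#' @param rotation 3x3 matrix applied on the left.
#' @param translation length-3 offset added after rotation.
#' @return transformed `tri_surface`.
#' @export
transform_surface <- function(surface, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- surface$vertices %*% t(rotation)
  v <- sweep(v, 2L, as.numeric(translation), "+")
  structure(list(vertices = v, faces = surface$faces), class = "tri_surface")
}
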