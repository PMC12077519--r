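#' Load a triangle mesh from PLY, OBJ or STL
#'
#' Reads ASCII PLY, ASCII OBJ, and ASCII or binary STL files into a
#' [tri_surface()]. The mesh is cleaned on load: duplicate vertices are
#' merged and degenerate (zero-area) faces dropped. Quad faces in OBJ/PLY
#' are fan-triangulated; higher polygons raise a format error. Binary PLY
#' is not supported and raises a format error naming the element.
#'
#' @param path file path.
#' @param format one of `"PLY"`, `"OBJ"`, `"STL"`; guessed from the file
#'   extension when missing.
#' @return a cleaned [tri_surface()].
#' @export
load_surface <- function(path, format = NULL) {
  if (!file.exists(path)) stop("mesh file does not exist: ", path)
  if (is.null(format)) {
    ext <- toupper(tools::file_ext(path))
    if (!ext %in% c("PLY", "OBJ", "STL"))
      stop("cannot guess mesh format from extension '", ext, "'; pass format=")
    format <- ext
  }
  format <- toupper(format)
  s <- switch(format,
    PLY = read_ply(path),
    OBJ = read_obj(path),
    STL = read_stl(path),
    stop("unsupported mesh format: ", format)
  )
  tri_surface(s$vertices, s$faces, clean = TRUE)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1L]) != "ply")
    stop("PLY format error: missing 'ply' magic line in ", path)
  hdr_end <- which(trimws(lines) == "end_header")[1L]
  if (is.na(hdr_end)) stop("PLY format error: no 'end_header' in ", path)
  hdr <- trimws(lines[seq_len(hdr_end)])
  fmt <- grep("^format ", hdr, value = TRUE)
  if (length(fmt) == 0L) stop("PLY format error: missing 'format' element")
  if (!grepl("ascii", fmt[1L]))
    stop("PLY format error: binary PLY is not supported (element 'format': ",
         fmt[1L], "); convert to ascii")
  el <- grep("^element ", hdr)
  nv <- nf <- NA_integer_
  for (i in el) {
    tok <- strsplit(hdr[i], "\\s+")[[1L]]
    if (tok[2L] == "vertex") nv <- as.integer(tok[3L])
    if (tok[2L] == "face") nf <- as.integer(tok[3L])
  }
  if (is.na(nv)) stop("PLY format error: missing element 'vertex'")
  if (is.na(nf)) nf <- 0L
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop("PLY format error: truncated body")
  vtok <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- t(vapply(vtok, function(t) as.numeric(t[1:3]), numeric(3)))
  faces <- matrix(integer(0), 0L, 3L)
  if (nf > 0L) {
    ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    faces <- do.call(rbind, lapply(ftok, function(t) {
      k <- as.integer(t[1L])
      idx <- as.integer(t[1L + seq_len(k)]) + 1L
      if (k == 3L) matrix(idx, 1L, 3L)
      else if (k == 4L) rbind(idx[c(1L, 2L, 3L)], idx[c(1L, 3L, 4L)])
      else stop("PLY format error: face with ", k, " vertices (element 'face')")
    }))
  }
  list(vertices = verts, faces = faces)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (length(vlines) == 0L) stop("OBJ format error: no vertex ('v') records in ", path)
  verts <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                    function(t) as.numeric(t[2:4]), numeric(3)))
  faces <- matrix(integer(0), 0L, 3L)
  if (length(flines) > 0L) {
    faces <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(t) {
      idx <- as.integer(vapply(strsplit(t[-1L], "/"), `[`, "", 1L))
      k <- length(idx)
      if (k == 3L) matrix(idx, 1L, 3L)
      else if (k == 4L) rbind(idx[c(1L, 2L, 3L)], idx[c(1L, 3L, 4L)])
      else stop("OBJ format error: face ('f') with ", k, " vertices")
    }))
  }
  list(vertices = verts, faces = faces)
}

read_stl <- function(path) {
  # ASCII STL begins with 'solid' AND contains 'facet'; binary otherwise
  head <- readBin(path, "raw", n = 512L)
  txt <- rawToChar(head[head != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, useBytes = TRUE)
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- grep("^vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("STL format error: vertex count not a multiple of 3 in ", path)
  verts <- t(vapply(strsplit(vl, "\\s+"), function(t) as.numeric(t[2:4]), numeric(3)))
  faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(nf) || nf < 0L || nf > 5e7)
    stop("STL format error: implausible facet count in binary header of ", path)
  verts <- matrix(0, nf * 3L, 3L)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    if (length(rec) < 12L) stop("STL format error: truncated binary facet ", i)
    verts[3L * i - 2L, ] <- rec[4:6]
    verts[3L * i - 1L, ] <- rec[7:9]
    verts[3L * i, ] <- rec[10:12]
    readBin(con, "raw", n = 2L)
  }
  list(vertices = verts, faces = matrix(seq_len(nf * 3L), ncol = 3L, byrow = TRUE))
}

#' Write a surface to ASCII PLY
#'
#' @param surface a [tri_surface()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(surface, path) {
  v <- surface$vertices
  f <- surface$faces
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nrow(v)),
           "property double x", "property double y", "property double z",
           paste("element face", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  vl <- sprintf("%.10g %.10g %.10g", v[, 1L], v[, 2L], v[, 3L])
  fl <- sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}
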