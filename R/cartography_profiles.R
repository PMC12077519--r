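#' Standardize a thickness map by bone length
#'
#' Divides every cell by the bone's maximum length, making maps
#' dimensionless and comparable across body sizes. Standardizing twice is
#' a contract error.
#'
#' @param map a `thickness_map`.
#' @return standardized `thickness_map`.
#' @export
standardize_map <- function(map) {
  stopifnot(inherits(map, "thickness_map"))
  if (isTRUE(map$standardized))
    stop("contract error: map is already standardized")
  if (!is.finite(map$bone_length) || map$bone_length <= 0)
    stop("bone_length must be positive")
  map$values <- map$values / map$bone_length
  map$standardized <- TRUE
  map
}

.check_same_grid <- function(maps) {
  d1 <- dim(maps[[1L]]$values)
  for (m in maps) {
    if (!identical(dim(m$values), d1)) stop("maps have mixed grids")
    if (max(abs(m$levels - maps[[1L]]$levels)) > 1e-9) stop("maps have mixed level grids")
  }
  std <- vapply(maps, function(m) isTRUE(m$standardized), logical(1))
  if (length(unique(std)) > 1L)
    stop("maps have mixed standardization states")
  invisible(std[1L])
}

#' Entrywise mean of thickness maps
#'
#' Flagged (solid-section) cells are excluded per cell; the per-cell
#' count of contributing maps is carried in `meta$n_contributing`.
#'
#' @param maps list of `thickness_map`s on the same grid and in the same
#'   standardization state.
#' @param require_standardized error unless all maps are standardized.
#' @return mean `thickness_map` (bone_length = mean of inputs).
#' @export
mean_map <- function(maps, require_standardized = FALSE) {
  stopifnot(length(maps) >= 1L)
  std <- .check_same_grid(maps)
  if (require_standardized && !std)
    stop("mean_map requires standardized maps")
  vals <- lapply(maps, function(m) { v <- m$values; v[m$mask] <- NA_real_; v })
  arr <- simplify2array(vals)
  n_ok <- apply(!is.na(arr), c(1L, 2L), sum)
  mv <- apply(arr, c(1L, 2L), function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
  mask <- n_ok == 0L
  mv[mask] <- 0
  m1 <- maps[[1L]]
  structure(list(values = mv, mask = mask, levels = m1$levels, angles = m1$angles,
                 bone_length = mean(vapply(maps, `[[`, 0, "bone_length")),
                 standardized = std,
                 meta = list(n_maps = length(maps), n_contributing = n_ok)),
            class = "thickness_map")
}

#' Per-individual digit-mean map
#'
#' Averages the standardized maps of one individual's rays 2-5 (or
#' whichever digits are preserved) within one element type, recording the
#' contributing digits.
#'
#' @param maps 1-4 standardized `thickness_map`s from one individual,
#'   all PP or all IP.
#' @return mean `thickness_map` with `meta$digits`.
#' @export
digit_mean <- function(maps) {
  stopifnot(length(maps) >= 1L, length(maps) <= 4L)
  elements <- vapply(maps, function(m) as.character(m$meta$element %||% NA), "")
  if (length(unique(elements)) > 1L)
    stop("digit_mean: mixed PP/IP inputs")
  std <- vapply(maps, function(m) isTRUE(m$standardized), logical(1))
  if (!all(std)) stop("digit_mean requires standardized maps")
  out <- mean_map(maps, require_standardized = TRUE)
  out$meta$digits <- sort(vapply(maps, function(m) as.integer(m$meta$digit %||% NA), 0L))
  out$meta$element <- elements[1L]
  out$meta$id <- maps[[1L]]$meta$id
  out$meta$label <- maps[[1L]]$meta$label
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Proximodistal mean-thickness profile
#'
#' Per-level mean over the 50 angular cells, flagged cells excluded; a
#' fully masked row is reported as missing (NA), never zero.
#'
#' @param map a `thickness_map`.
#' @return object of class `thickness_profile` with `levels` (fractions)
#'   and `mean_thickness`.
#' @export
thickness_profile <- function(map) {
  stopifnot(inherits(map, "thickness_map"))
  v <- map$values
  v[map$mask] <- NA_real_
  prof <- rowMeans(v, na.rm = TRUE)
  prof[is.nan(prof)] <- NA_real_
  structure(list(levels = map$levels, mean_thickness = prof,
                 standardized = map$standardized, meta = map$meta),
            class = "thickness_profile")
}

#' Location of the profile peak
#'
#' The level (shaft-length fraction) of the profile maximum after a
#' centered moving-average smoothing (default window 5 rows, about 5
#' percent of shaft length). Ties break toward the proximal-most
#' maximizer.
#'
#' @param profile a `thickness_profile`.
#' @param smooth_window odd moving-average window in rows; 1 disables
#'   smoothing.
#' @return peak level fraction.
#' @export
profile_peak <- function(profile, smooth_window = 5L) {
  y <- profile$mean_thickness
  if (sum(!is.na(y)) < 3L) stop("profile has fewer than 3 non-missing values")
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L) stop("smooth_window must be odd")
    h <- (smooth_window - 1L) %/% 2L
    n <- length(y)
    ys <- vapply(seq_len(n), function(i) {
      win <- y[max(1L, i - h):min(n, i + h)]
      mean(win, na.rm = TRUE)
    }, 0)
    ys[is.nan(ys)] <- NA_real_
  } else ys <- y
  i <- which(ys >= max(ys, na.rm = TRUE) - 1e-12)[1L]
  profile$levels[i]
}

#' Whole-shaft mean cortical thickness
#'
#' Mean over all non-flagged map cells; standardized iff the map is.
#'
#' @param map a `thickness_map`.
#' @return scalar mean thickness.
#' @export
mean_cortical_thickness <- function(map) {
  stopifnot(inherits(map, "thickness_map"))
  ok <- !map$mask
  if (!any(ok)) stop("all cells are flagged")
  mean(map$values[ok])
}

#' Write a thickness map as CSV (+ JSON metadata and mask)
#'
#' The CSV has one row per level with an index column of level fractions
#' and a header of ray angles in degrees. The mask and metadata are
#' written alongside (`*_mask.csv`, `*.json`).
#'
#' @param map a `thickness_map`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  df <- as.data.frame(map$values)
  names(df) <- sprintf("deg_%g", round(map$angles * 180 / pi, 2))
  df <- cbind(level_frac = map$levels, df)
  utils::write.csv(df, path, row.names = FALSE)
  maskdf <- cbind(level_frac = map$levels, as.data.frame(map$mask * 1L))
  names(maskdf) <- names(df)
  utils::write.csv(maskdf, sub("\\.csv$", "_mask.csv", path), row.names = FALSE)
  meta <- map$meta
  meta$bone_length <- map$bone_length
  meta$standardized <- map$standardized
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a thickness map written by [write_map_csv()]
#'
#' @param path CSV path.
#' @return a `thickness_map`.
#' @export
read_map_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  levels <- df[[1L]]
  values <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(values) <- NULL
  angles <- as.numeric(sub("deg_", "", names(df)[-1L])) * pi / 180
  maskpath <- sub("\\.csv$", "_mask.csv", path)
  mask <- if (file.exists(maskpath)) {
    m <- as.matrix(utils::read.csv(maskpath, check.names = FALSE)[, -1L]) > 0
    dimnames(m) <- NULL
    m
  } else matrix(FALSE, nrow(values), ncol(values))
  jsonpath <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(jsonpath)) jsonlite::read_json(jsonpath, simplifyVector = TRUE) else list()
  bl <- meta$bone_length %||% NA_real_
  std <- isTRUE(meta$standardized)
  meta$bone_length <- NULL; meta$standardized <- NULL
  structure(list(values = values, mask = mask, levels = levels, angles = angles,
                 bone_length = bl, standardized = std, meta = meta),
            class = "thickness_map")
}

#' Render a thickness map as a PNG heat map
#'
#' Unrolled 2D rendering (angle on x from mid-dorsal, level on y from
#' proximal at the bottom) with a perceptually uniform palette. The data
#' CSV is written alongside, and the color-scale limits are recorded in
#' the metadata JSON.
#'
#' @param map a `thickness_map`.
#' @param path PNG output path.
#' @param zlim optional fixed color-scale limits, for shared scales
#'   across maps.
#' @param width,height image size in pixels.
#' @return `path`, invisibly.
#' @export
export_map_image <- function(map, path, zlim = NULL, width = 700, height = 900) {
  if (is.null(zlim)) zlim <- range(map$values)
  if (diff(zlim) == 0) zlim <- zlim + c(-1, 1) * max(1e-6, abs(zlim[1L]) * 1e-6)
  csvpath <- sub("\\.png$", ".csv", path)
  write_map_csv(map, csvpath)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", csvpath), simplifyVector = TRUE)
  meta$color_scale <- zlim
  jsonlite::write_json(meta, sub("\\.csv$", ".json", csvpath), auto_unbox = TRUE,
                       digits = NA)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(256, "viridis")
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::image(x = map$angles * 180 / pi, y = map$levels * 100,
                  z = t(map$values), zlim = zlim, col = pal,
                  xlab = "angle from mid-dorsal (deg)",
                  ylab = "shaft level (% proximal to distal)",
                  main = map$meta$id %||% "", useRaster = TRUE)
  invisible(path)
}
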