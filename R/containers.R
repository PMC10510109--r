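#' Rectangular study region
#'
#' A plasma-membrane sheet (or TIRF field of view) is modelled as an axis-
#' aligned rectangle with its origin at the lower-left corner. Units are
#' whatever the caller uses consistently (nm for EM sheets, um for tracking).
#'
#' @param width,height Positive side lengths.
#' @param unit Unit label carried along for display and CSV headers
#'   (default `"nm"`).
#' @return An object of class `"region"` with fields `width`, `height`,
#'   `unit` and `area`.
#' @examples
#' region(1000, 1000)           # the 1 um^2 EM sheet default
#' region(16, 16, unit = "um")  # a TIRF field of view
#' @export
region <- function(width, height, unit = "nm") {
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0) {
    stopf("`width` must be a single positive number (got %s)", format(width)[1])
  }
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) || height <= 0) {
    stopf("`height` must be a single positive number (got %s)", format(height)[1])
  }
  structure(
    list(width = as.numeric(width), height = as.numeric(height),
         unit = as.character(unit), area = as.numeric(width) * as.numeric(height)),
    class = "region"
  )
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("region: %g x %g %s (area %g %s^2)\n",
              x$width, x$height, x$unit, x$area, x$unit))
  invisible(x)
}

#' Planar point pattern on a rectangular region
#'
#' The unit of EM spatial analysis: gold-particle coordinates observed on
#' one plasma-membrane sheet. Points outside the region are rejected; exact
#' duplicate points are allowed but logged, since two gold particles can
#' project to indistinguishable coordinates.
#'
#' @param x,y Numeric coordinate vectors (same length), in the region's unit.
#' @param region A [region()].
#' @param sheet_id Optional label for the sheet the pattern came from.
#' @return Object of class `"point_pattern"`: list with `x`, `y`, `region`,
#'   `sheet_id` and point count `n`.
#' @export
point_pattern <- function(x, y, region, sheet_id = NA_character_) {
  stopifnot(inherits(region, "region"))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stopf("x and y differ in length (%d vs %d)", length(x), length(y))
  if (anyNA(x) || anyNA(y)) stopf("point coordinates must be finite (NA found)")
  if (length(x) > 0 &&
      (min(x) < 0 || max(x) > region$width || min(y) < 0 || max(y) > region$height)) {
    stopf("all points must lie inside the region [0, %g] x [0, %g] %s",
          region$width, region$height, region$unit)
  }
  if (anyDuplicated(cbind(x, y))) {
    mn_log("point_pattern: exact duplicate coordinates present (kept)")
  }
  structure(
    list(x = x, y = y, region = region, sheet_id = sheet_id, n = length(x)),
    class = "point_pattern"
  )
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points on %g x %g %s sheet%s\n",
              x$n, x$region$width, x$region$height, x$region$unit,
              if (is.na(x$sheet_id)) "" else sprintf(" [%s]", x$sheet_id)))
  invisible(x)
}

#' @export
plot.point_pattern <- function(x, ..., pch = 16, cex = 0.5, asp = 1) {
  plot(x$x, x$y, xlim = c(0, x$region$width), ylim = c(0, x$region$height),
       xlab = sprintf("x (%s)", x$region$unit), ylab = sprintf("y (%s)", x$region$unit),
       pch = pch, cex = cex, asp = asp, ...)
  graphics::rect(0, 0, x$region$width, x$region$height, border = "grey40")
  invisible(x)
}

#' Generic (abscissa, signal) curve trace
#'
#' Carrier for the assay curves the package fits: TRACT relaxation decays,
#' DSF melt curves, DLS scattering-vs-log-concentration series and FLIM
#' fluorescence decays. The abscissa must be strictly increasing.
#'
#' @param x Strictly increasing abscissa values.
#' @param y Signal values, same length as `x`.
#' @param kind One of `"tract"`, `"melt"`, `"dls"`, `"flim"` or another label.
#' @param x_unit,y_unit Unit labels (e.g. `"s"`, `"degC"`, `"log10_nM"`, `"ns"`).
#' @return Object of class `"curve_trace"`.
#' @export
curve_trace <- function(x, y, kind, x_unit = "", y_unit = "au") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stopf("x and y differ in length (%d vs %d)", length(x), length(y))
  if (length(x) < 2L) stopf("a curve trace needs at least 2 points")
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("curve values must be finite")
  if (any(diff(x) <= 0)) stopf("abscissa must be strictly increasing")
  structure(list(x = x, y = y, kind = as.character(kind),
                 x_unit = x_unit, y_unit = y_unit),
            class = "curve_trace")
}

#' @export
print.curve_trace <- function(x, ...) {
  cat(sprintf("curve trace [%s]: %d points, x in [%g, %g] %s\n",
              x$kind, length(x$x), min(x$x), max(x$x), x$x_unit))
  invisible(x)
}

#' @export
plot.curve_trace <- function(x, ..., type = "b", pch = 16, cex = 0.6) {
  plot(x$x, x$y, type = type, pch = pch, cex = cex,
       xlab = sprintf("x (%s)", x$x_unit), ylab = sprintf("y (%s)", x$y_unit),
       main = x$kind, ...)
  invisible(x)
}

#' Set of linked single-particle trajectories
#'
#' @param tracks Data frame with columns `track_id`, `frame`, `x`, `y`
#'   (positions in um unless stated otherwise; 0-based frame indices).
#' @param frame_interval Time between frames in seconds (default 0.010 s).
#' @param unit Position unit label.
#' @return Object of class `"track_set"`.
#' @export
track_set <- function(tracks, frame_interval = 0.010, unit = "um") {
  stopifnot(is.data.frame(tracks))
  need <- c("track_id", "frame", "x", "y")
  miss <- setdiff(need, names(tracks))
  if (length(miss)) stopf("track table missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(tracks)) {
    o <- order(tracks$track_id, tracks$frame)
    tracks <- tracks[o, , drop = FALSE]
    rownames(tracks) <- NULL
    if (any(stats::ave(tracks$frame, tracks$track_id,
                       FUN = function(f) c(1, diff(f))) <= 0)) {
      stopf("frames within a track must be strictly increasing")
    }
  }
  structure(list(tracks = tracks, frame_interval = frame_interval, unit = unit),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  n_tr <- length(unique(x$tracks$track_id))
  cat(sprintf("track set: %d tracks, %d localizations, dt = %g s\n",
              n_tr, nrow(x$tracks), x$frame_interval))
  invisible(x)
}

#' @export
plot.track_set <- function(x, ..., max_tracks = 50) {
  ids <- unique(x$tracks$track_id)
  ids <- ids[seq_len(min(length(ids), max_tracks))]
  sub <- x$tracks[x$tracks$track_id %in% ids, ]
  plot(sub$x, sub$y, type = "n",
       xlab = sprintf("x (%s)", x$unit), ylab = sprintf("y (%s)", x$unit), ...)
  cols <- grDevices::hcl.colors(length(ids), "Dark 3")
  for (i in seq_along(ids)) {
    tr <- sub[sub$track_id == ids[i], ]
    graphics::lines(tr$x, tr$y, col = cols[i])
  }
  invisible(x)
}
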