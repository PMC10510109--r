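#' Read and validate a CSV table against a schema
#'
#' Shared entry point for every table the package consumes. The schema
#' names the required columns and their types; missing columns, empty
#' files and non-numeric cells are reported by name. Pixel-unit position
#' columns (`*_px`) are converted to um when the schema asks for `*_um`
#' and a `pixel_size` is supplied; without one, the error says which
#' option to pass.
#'
#' @param path CSV file path (comma-separated, dot decimal, header row
#'   mandatory, UTF-8).
#' @param schema Named character vector: column name -> type
#'   (`"numeric"`, `"integer"` or `"character"`).
#' @param pixel_size Optional um/px conversion used when a `*_um` column
#'   is only available as `*_px`.
#' @return A validated data frame with the schema's columns.
#' @export
load_table <- function(path, schema, pixel_size = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stopf("empty table: %s", path)
  for (col in names(schema)) {
    if (!col %in% names(df)) {
      px_alias <- sub("_um$", "_px", col)
      if (grepl("_um$", col) && px_alias %in% names(df)) {
        if (is.null(pixel_size)) {
          stopf("column `%s` is in pixel units (`%s`); supply `pixel_size` (CLI: --pixel-size) to convert to um",
                col, px_alias)
        }
        df[[col]] <- as.numeric(df[[px_alias]]) * pixel_size
      } else {
        stopf("missing column `%s` in %s", col, path)
      }
    }
    type <- schema[[col]]
    if (type %in% c("numeric", "integer")) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      if (anyNA(v) && !anyNA(df[[col]])) {
        stopf("non-numeric value in column `%s` of %s", col, path)
      }
      if (anyNA(v)) stopf("missing value in column `%s` of %s", col, path)
      df[[col]] <- if (type == "integer") as.integer(v) else v
    } else {
      df[[col]] <- as.character(df[[col]])
    }
  }
  mn_log(sprintf("load_table: %s -> %d rows", path, nrow(df)))
  df[, names(schema), drop = FALSE]
}

#' Write/read gold-particle point patterns
#'
#' The on-disk format is `sheet_id,x_nm,y_nm`; the region is metadata the
#' CSV does not carry and must be supplied on read.
#'
#' @param patterns A [point_pattern()] or list of them.
#' @param path CSV path.
#' @return `write_points_csv` returns `path` invisibly; `read_points_csv`
#'   returns a named list of [point_pattern()] objects, one per sheet.
#' @export
write_points_csv <- function(patterns, path) {
  if (inherits(patterns, "point_pattern")) patterns <- list(patterns)
  rows <- lapply(patterns, function(p) {
    data.frame(sheet_id = if (is.na(p$sheet_id)) "sheet1" else p$sheet_id,
               x_nm = p$x, y_nm = p$y)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @param region A [region()] shared by all sheets in the file.
#' @export
read_points_csv <- function(path, region) {
  df <- load_table(path, c(sheet_id = "character", x_nm = "numeric", y_nm = "numeric"))
  lapply(split(df, df$sheet_id), function(s) {
    point_pattern(s$x_nm, s$y_nm, region, sheet_id = s$sheet_id[1])
  })
}

#' Write/read single-particle track tables
#'
#' Format: `track_id,frame,x_um,y_um` with 0-based frames.
#'
#' @param tracks A [track_set()] with positions in um.
#' @param path CSV path.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  tb <- tracks$tracks
  utils::write.csv(data.frame(track_id = tb$track_id, frame = tb$frame,
                              x_um = tb$x, y_um = tb$y),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @param frame_interval Frame time in seconds.
#' @param pixel_size Optional um/px conversion if the file holds pixel columns.
#' @export
read_tracks_csv <- function(path, frame_interval = 0.010, pixel_size = NULL) {
  df <- load_table(path, c(track_id = "integer", frame = "integer",
                           x_um = "numeric", y_um = "numeric"),
                   pixel_size = pixel_size)
  track_set(data.frame(track_id = df$track_id, frame = df$frame,
                       x = df$x_um, y = df$y_um),
            frame_interval, unit = "um")
}

#' Write/read generic assay curves
#'
#' The two-column format carries its units in the header
#' (`x_<unit>,y_<unit>`), e.g. `x_degC,y_au`.
#'
#' @param trace A [curve_trace()].
#' @param path CSV path.
#' @export
write_curve_csv <- function(trace, path) {
  stopifnot(inherits(trace, "curve_trace"))
  df <- data.frame(trace$x, trace$y)
  names(df) <- c(paste0("x_", if (nzchar(trace$x_unit)) trace$x_unit else "au"),
                 paste0("y_", trace$y_unit))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @param kind Curve kind label to attach (default `"unknown"`).
#' @export
read_curve_csv <- function(path, kind = "unknown") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stopf("curve CSV needs two columns (x_<unit>,y_<unit>): %s", path)
  xu <- sub("^x_", "", names(df)[1]); yu <- sub("^y_", "", names(df)[2])
  curve_trace(df[[1]], df[[2]], kind = kind, x_unit = xu, y_unit = yu)
}

#' Write/read NMR peak and intensity tables
#'
#' Peak tables: `residue,H_ref_ppm,N_ref_ppm,H_alt_ppm,N_alt_ppm`;
#' intensity tables: `residue,I_tagged,I_untagged`.
#'
#' @param peaks,intensities Data frames in the formats above.
#' @param path CSV path.
#' @export
write_peaks_csv <- function(peaks, path) {
  utils::write.csv(peaks, path, row.names = FALSE); invisible(path)
}

#' @rdname write_peaks_csv
#' @export
read_peaks_csv <- function(path) {
  load_table(path, c(residue = "integer", H_ref_ppm = "numeric", N_ref_ppm = "numeric",
                     H_alt_ppm = "numeric", N_alt_ppm = "numeric"))
}

#' @rdname write_peaks_csv
#' @export
write_intensities_csv <- function(intensities, path) {
  utils::write.csv(intensities, path, row.names = FALSE); invisible(path)
}

#' @rdname write_peaks_csv
#' @export
read_intensities_csv <- function(path) {
  load_table(path, c(residue = "integer", I_tagged = "numeric", I_untagged = "numeric"))
}

#' Write/read frame stacks as 16-bit multi-page TIFF
#'
#' Counts are stored as 16-bit unsigned integers (values above 65534 are
#' clipped; rendering at sane photon budgets stays far below that).
#'
#' @param stack A [render_frames()] result.
#' @param path TIFF path.
#' @export
write_frames_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(f) {
    m <- stack$frames[, , f]
    pmin(pmax(round(m), 0), 65534) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_frames_tiff
#' @param pixel_size um/px recorded on the returned object.
#' @param psf_sigma PSF width in px recorded on the returned object.
#' @export
read_frames_tiff <- function(path, pixel_size = 0.16, psf_sigma = 1.3) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- round(pages[[f]] * 65535)
  structure(list(frames = arr, pixel_size = pixel_size, psf_sigma = psf_sigma),
            class = "frame_stack")
}
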