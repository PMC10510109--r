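#' Render localisations into synthetic camera frames
#'
#' Turns observed track positions into a movie for testing spot detection:
#' each localisation becomes an integrated symmetric 2D Gaussian (total
#' intensity `photons` spread according to the PSF), on top of a uniform
#' background, with optional Poisson counting noise. Pixel centres sit at
#' integer pixel coordinates (0-based); a position in um maps to pixel
#' coordinates as `x / pixel_size`.
#'
#' @param tracks A [track_set()] with positions in um.
#' @param psf_sigma PSF standard deviation in pixels (default 1.3).
#' @param pixel_size Pixel pitch in um/px (default 0.16, i.e. 100 px = 16 um).
#' @param photons Expected total counts per emitter per frame.
#' @param background Expected background counts per pixel.
#' @param dims Frame size `c(nx, ny)` in pixels; by default derived from
#'   the region recorded nowhere, so 100 x 100.
#' @param poisson_noise Apply Poisson counting noise (default TRUE). With
#'   `FALSE` the noiseless expected image is returned, useful for
#'   calibration tests.
#' @param n_frames Number of frames; defaults to `max(frame) + 1`.
#' @param seed Integer seed (used only when `poisson_noise = TRUE`).
#' @return Object of class `"frame_stack"`: list with `frames` (3D array
#'   `[ny, nx, n_frames]` of counts), `pixel_size`, `psf_sigma`.
#' @export
render_frames <- function(tracks, psf_sigma = 1.3, pixel_size = 0.16,
                          photons = 1000, background = 10,
                          dims = c(100L, 100L), poisson_noise = TRUE,
                          n_frames = NULL, seed = 1L) {
  stopifnot(inherits(tracks, "track_set"))
  if (psf_sigma <= 0) stopf("`psf_sigma` must be > 0")
  if (pixel_size <= 0) stopf("`pixel_size` must be > 0")
  nx <- as.integer(dims[1]); ny <- as.integer(dims[2])
  tb <- tracks$tracks
  if (is.null(n_frames)) {
    n_frames <- if (nrow(tb)) max(tb$frame) + 1L else 1L
  }
  stack <- array(as.numeric(background), dim = c(ny, nx, n_frames))
  n_clipped <- 0L
  if (nrow(tb)) {
    xpx <- tb$x / pixel_size
    ypx <- tb$y / pixel_size
    # pixel i covers [i - 0.5, i + 0.5]; emitters whose centre is off-frame
    # are clipped (not rendered) and counted
    for (r in seq_len(nrow(tb))) {
      f <- tb$frame[r] + 1L
      if (f > n_frames) next
      x0 <- xpx[r]; y0 <- ypx[r]
      if (x0 < -0.5 || x0 > nx - 0.5 || y0 < -0.5 || y0 > ny - 0.5) {
        n_clipped <- n_clipped + 1L
        next
      }
      half <- ceiling(4 * psf_sigma)
      ix <- max(0L, floor(x0) - half):min(nx - 1L, ceiling(x0) + half)
      iy <- max(0L, floor(y0) - half):min(ny - 1L, ceiling(y0) + half)
      gx <- stats::pnorm((ix + 0.5 - x0) / psf_sigma) -
            stats::pnorm((ix - 0.5 - x0) / psf_sigma)
      gy <- stats::pnorm((iy + 0.5 - y0) / psf_sigma) -
            stats::pnorm((iy - 0.5 - y0) / psf_sigma)
      stack[iy + 1L, ix + 1L, f] <- stack[iy + 1L, ix + 1L, f] +
        photons * outer(gy, gx)
    }
  }
  if (n_clipped > 0) mn_log(sprintf("render_frames: %d localisations outside the frame were clipped", n_clipped))
  if (poisson_noise) {
    stack <- with_seed(seed, {
      array(stats::rpois(length(stack), stack), dim = dim(stack))
    })
  }
  structure(list(frames = stack, pixel_size = pixel_size, psf_sigma = psf_sigma),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame stack: %d frames of %d x %d px (%g um/px)\n",
              d[3], d[2], d[1], x$pixel_size))
  invisible(x)
}
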