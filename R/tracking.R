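#' Detect fluorescent spots in a single frame
#'
#' GLRT-style matched-filter detection followed by Gaussian refinement,
#' emulating localisation-microscopy spot finders: at every pixel the local
#' window is regressed on a centred Gaussian template of width `psf_sigma`
#' and the generalised likelihood-ratio statistic
#' `T = -N * log(1 - rho^2)` (N window pixels, rho the template
#' correlation, positive amplitudes only) is compared against
#' `sensitivity`. Supra-threshold pixels are merged by 8-way adjacency into
#' one candidate per connected component, and each candidate is refined by
#' least-squares fitting of a symmetric 2D Gaussian with the PSF width
#' fixed, giving sub-pixel positions. Detections within `psf_sigma` of the
#' frame border are dropped.
#'
#' @param frame_image Numeric matrix of counts (rows = y, columns = x;
#'   pixel centres at integer 0-based coordinates).
#' @param sensitivity GLRT threshold (default 30).
#' @param psf_sigma PSF standard deviation in pixels (default 1.3).
#' @return Data frame with one row per detection: `x`, `y` (px, 0-based),
#'   `amplitude`, `background`, `sigma`, `glrt`.
#' @export
detect_spots <- function(frame_image, sensitivity = 30, psf_sigma = 1.3) {
  if (!is.matrix(frame_image) || !length(frame_image)) stopf("`frame_image` must be a non-empty matrix")
  if (psf_sigma <= 0) stopf("`psf_sigma` must be > 0")
  if (sensitivity <= 0) stopf("`sensitivity` must be > 0")
  bad <- which(!is.finite(frame_image) | frame_image >= 65535)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(frame_image))
    stopf("saturated or non-finite pixel at row %d, column %d", rc[1], rc[2])
  }
  ny <- nrow(frame_image); nx <- ncol(frame_image)
  half <- ceiling(3 * psf_sigma)
  win <- (2L * half + 1L)
  if (nx < win || ny < win) stopf("frame smaller than the %d px detection window", win)
  N <- win * win
  off <- -half:half
  g <- exp(-outer(off^2, off^2, "+") / (2 * psf_sigma^2))
  gbar <- mean(g)
  gc <- g - gbar
  sgg <- sum(gc^2)

  # window sums via shift-and-add over the (2*half+1)^2 offsets
  Sy <- matrix(0, ny, nx); Syy <- matrix(0, ny, nx); Sgy <- matrix(0, ny, nx)
  core_r <- (half + 1L):(ny - half)
  core_c <- (half + 1L):(nx - half)
  for (dy in off) for (dx in off) {
    blk <- frame_image[core_r + dy, core_c + dx, drop = FALSE]
    Sy[core_r, core_c]  <- Sy[core_r, core_c] + blk
    Syy[core_r, core_c] <- Syy[core_r, core_c] + blk^2
    Sgy[core_r, core_c] <- Sgy[core_r, core_c] + g[dy + half + 1L, dx + half + 1L] * blk
  }
  num <- Sgy - gbar * Sy              # amplitude direction (positive spots only)
  ssy <- Syy - Sy^2 / N
  rho2 <- ifelse(ssy > 0 & num > 0, pmin(num^2 / (sgg * ssy), 1 - 1e-12), 0)
  glrt <- -N * log(1 - rho2)
  glrt[-core_r, ] <- -Inf
  glrt[, -core_c] <- -Inf

  cand <- which(glrt > sensitivity, arr.ind = TRUE)
  if (!nrow(cand)) {
    return(data.frame(x = numeric(0), y = numeric(0), amplitude = numeric(0),
                      background = numeric(0), sigma = numeric(0), glrt = numeric(0)))
  }
  comp <- label_components8(cand)
  out <- vector("list", max(comp))
  for (k in seq_len(max(comp))) {
    px <- cand[comp == k, , drop = FALSE]
    seed_i <- which.max(glrt[px])
    r0 <- px[seed_i, 1]; c0 <- px[seed_i, 2]
    fit <- fit_gaussian_spot(frame_image, r0, c0, half, psf_sigma)
    if (is.null(fit)) next
    # drop detections hugging the border
    if (fit$x < psf_sigma || fit$x > nx - 1 - psf_sigma ||
        fit$y < psf_sigma || fit$y > ny - 1 - psf_sigma) next
    fit$glrt <- glrt[r0, c0]
    out[[k]] <- fit
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(x = numeric(0), y = numeric(0), amplitude = numeric(0),
                      background = numeric(0), sigma = numeric(0), glrt = numeric(0)))
  }
  do.call(rbind, lapply(out, as.data.frame))
}

# 8-connectivity components of candidate pixels (matrix of row/col indices).
label_components8 <- function(cand) {
  n <- nrow(cand)
  lab <- integer(n)
  cur <- 0L
  key <- cand[, 1] * 1e6 + cand[, 2]
  idx <- split(seq_len(n), key)  # fast lookup by packed coordinate
  for (s in seq_len(n)) {
    if (lab[s]) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        kk <- as.character((cand[i, 1] + dy) * 1e6 + (cand[i, 2] + dx))
        nb <- idx[[kk]]
        if (!is.null(nb) && any(lab[nb] == 0L)) {
          nb <- nb[lab[nb] == 0L]
          lab[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}

# Least-squares symmetric Gaussian fit in a window about (r0, c0);
# sigma fixed at the PSF width. Returns x/y in 0-based pixel coordinates.
fit_gaussian_spot <- function(img, r0, c0, half, psf_sigma) {
  ny <- nrow(img); nx <- ncol(img)
  rows <- max(1L, r0 - half):min(ny, r0 + half)
  cols <- max(1L, c0 - half):min(nx, c0 + half)
  z <- img[rows, cols]
  xs <- cols - 1L  # 0-based pixel coordinates
  ys <- rows - 1L
  X <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  Y <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  b0 <- min(z); a0 <- max(z) - b0
  cx0 <- sum((z - b0) * X) / max(sum(z - b0), .Machine$double.eps)
  cy0 <- sum((z - b0) * Y) / max(sum(z - b0), .Machine$double.eps)
  obj <- function(p) {
    mu <- p[3] * exp(-((X - p[1])^2 + (Y - p[2])^2) / (2 * psf_sigma^2)) + p[4]
    sum((z - mu)^2)
  }
  fit <- try(stats::optim(c(cx0, cy0, a0, b0), obj, method = "Nelder-Mead",
                          control = list(maxit = 500, reltol = 1e-10)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  p <- fit$par
  if (p[3] <= 0) return(NULL)
  list(x = p[1], y = p[2], amplitude = p[3], background = p[4], sigma = psf_sigma)
}

#' Detect spots in every frame of a stack
#'
#' @param stack A [render_frames()] result or 3D array `[ny, nx, frames]`.
#' @inheritParams detect_spots
#' @return Data frame of localisations with a 0-based `frame` column
#'   prepended to the [detect_spots()] columns.
#' @export
detect_movie <- function(stack, sensitivity = 30, psf_sigma = 1.3) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  stopifnot(length(dim(frames)) == 3)
  out <- lapply(seq_len(dim(frames)[3]), function(f) {
    d <- detect_spots(frames[, , f], sensitivity, psf_sigma)
    if (nrow(d)) cbind(frame = f - 1L, d) else NULL
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      amplitude = numeric(0), background = numeric(0),
                      sigma = numeric(0), glrt = numeric(0)))
  }
  do.call(rbind, out)
}

#' Link localisations into tracks
#'
#' Greedy frame-by-frame nearest-neighbour linking with single-frame gap
#' closing, following the acquisition convention of the TIRF pipeline:
#' candidate (track end, new localisation) pairs are sorted by distance
#' and accepted in order when the distance is at most `max_jump`; a track
#' that missed the previous frame (blinking) may still be extended across
#' a gap of up to `max_gap` frames under the same distance bound. Each
#' localisation joins at most one track; unmatched localisations seed new
#' tracks. Tracks with fewer than `min_length` localisations are
#' discarded. Distance ties are broken in favour of the earlier track id,
#' which makes the result invariant to the input row order.
#'
#' @param locs Data frame with columns `frame`, `x`, `y` (any consistent
#'   spatial unit; defaults are in pixels, matching `max_jump`).
#' @param max_jump Maximum link distance (default 5, in the unit of `x`).
#' @param max_gap Maximum number of skipped frames (default 1).
#' @param min_length Minimum localisations per reported track (default 6).
#' @param frame_interval Frame time in seconds, stored on the result.
#' @param unit Position unit label.
#' @return A [track_set()].
#' @export
link_tracks <- function(locs, max_jump = 5, max_gap = 1, min_length = 6,
                        frame_interval = 0.010, unit = "px") {
  stopifnot(is.data.frame(locs))
  need <- c("frame", "x", "y")
  miss <- setdiff(need, names(locs))
  if (length(miss)) stopf("localisation table missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(locs) && is.unsorted(locs$frame)) {
    mn_log("link_tracks: input not sorted by frame; re-sorting")
  }
  locs <- locs[order(locs$frame, locs$x, locs$y), , drop = FALSE]
  n <- nrow(locs)
  track_of <- integer(n)
  last_idx <- integer(0)   # row index of each track's last localisation
  n_tracks <- 0L
  frames <- unique(locs$frame)
  for (f in frames) {
    rows <- which(locs$frame == f)
    active <- which(locs$frame[last_idx] >= f - 1L - max_gap & locs$frame[last_idx] < f)
    if (length(active) && length(rows)) {
      dx <- outer(locs$x[last_idx[active]], locs$x[rows], "-")
      dy <- outer(locs$y[last_idx[active]], locs$y[rows], "-")
      dmat <- sqrt(dx^2 + dy^2)
      ok <- which(dmat <= max_jump, arr.ind = TRUE)
      if (nrow(ok)) {
        ord <- order(dmat[ok], active[ok[, 1]])  # distance, then earlier track id
        used_track <- logical(length(active))
        used_loc <- logical(length(rows))
        for (ii in ord) {
          ti <- ok[ii, 1]; li <- ok[ii, 2]
          if (used_track[ti] || used_loc[li]) next
          used_track[ti] <- TRUE; used_loc[li] <- TRUE
          tr <- active[ti]
          track_of[rows[li]] <- tr
          last_idx[tr] <- rows[li]
        }
      }
    }
    for (r in rows) {
      if (track_of[r] == 0L) {
        n_tracks <- n_tracks + 1L
        track_of[r] <- n_tracks
        last_idx[n_tracks] <- r
      }
    }
  }
  tb <- data.frame(track_id = track_of, frame = locs$frame, x = locs$x, y = locs$y)
  keep_ids <- names(which(table(tb$track_id) >= min_length))
  tb <- tb[tb$track_id %in% as.integer(keep_ids), , drop = FALSE]
  if (nrow(tb)) tb$track_id <- as.integer(factor(tb$track_id))  # compact ids
  track_set(tb, frame_interval, unit = unit)
}

#' Pooled mean-square displacement
#'
#' Time-and-ensemble averaged MSD: for each lag `l` (in frames), averages
#' the squared displacement over every admissible observation pair
#' `(t, t + l)` pooled across all tracks. Pairs spanning a blink gap use
#' the true frame difference, so they contribute to their actual lag.
#'
#' @param tracks A [track_set()] (positions in um for physical units).
#' @param max_lag Largest lag in frames (default 10).
#' @return Object of class `"msd_curve"`: data frame `lag_frames`,
#'   `lag_s`, `msd`, `n_obs` (lags with no pairs are omitted and logged),
#'   plus the frame interval.
#' @export
compute_msd <- function(tracks, max_lag = 10) {
  stopifnot(inherits(tracks, "track_set"))
  if (max_lag < 1) stopf("`max_lag` must be >= 1")
  tb <- tracks$tracks
  if (!nrow(tb)) stopf("no tracks to analyse")
  max_lag <- as.integer(max_lag)
  ss <- numeric(max_lag); nn <- integer(max_lag)
  for (tr in split(tb, tb$track_id)) {
    m <- nrow(tr)
    if (m < 2) next
    for (lag in seq_len(max_lag)) {
      j <- match(tr$frame + lag, tr$frame)
      a <- which(!is.na(j)); b <- j[a]
      if (!length(a)) next
      ss[lag] <- ss[lag] + sum((tr$x[b] - tr$x[a])^2 + (tr$y[b] - tr$y[a])^2)
      nn[lag] <- nn[lag] + length(a)
    }
  }
  has <- nn > 0
  if (!all(has)) {
    mn_log(sprintf("compute_msd: %d of %d lags had no observation pairs and were omitted",
                   sum(!has), max_lag))
  }
  if (!any(has)) stopf("no valid observation pairs at any requested lag")
  structure(list(
    table = data.frame(lag_frames = which(has),
                       lag_s = which(has) * tracks$frame_interval,
                       msd = ss[has] / nn[has], n_obs = nn[has]),
    frame_interval = tracks$frame_interval, unit = tracks$unit
  ), class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve: %d lags, dt = %g s\n", nrow(x$table), x$frame_interval))
  print(utils::head(x$table, 5))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, ...) {
  plot(x$table$lag_s, x$table$msd, xlab = "lag (s)",
       ylab = sprintf("MSD (%s^2)", x$unit), pch = 16, ...)
  invisible(x)
}

#' Diffusion coefficient from the initial MSD slope
#'
#' Ordinary least squares of MSD on lag time over the first `n_lags`
#' reported lags. For 2D Brownian motion `MSD = 4 D t + 4 sigma_loc^2`,
#' so `D = slope / 4` and the intercept estimates four times the squared
#' localisation noise.
#'
#' @param msd A [compute_msd()] result.
#' @param n_lags Number of initial lags to fit (>= 2; default 4).
#' @return Object of class `"diffusion_fit"`: `D`, `intercept`,
#'   `intercept_se`, `D_se`, `n_lags_used`, `residual` (RSS), and a
#'   `negative_D` flag (a negative estimate is allowed but flagged).
#' @export
fit_diffusion <- function(msd, n_lags = 4) {
  stopifnot(inherits(msd, "msd_curve"))
  if (n_lags < 2) stopf("`n_lags` must be >= 2")
  tab <- utils::head(msd$table, n_lags)
  if (nrow(tab) < 2) stopf("fewer than 2 lags available for the fit")
  fit <- stats::lm(msd ~ lag_s, data = tab)
  co <- suppressWarnings(summary(fit))$coefficients  # exact lines trip lm's perfect-fit warning
  D <- unname(co["lag_s", "Estimate"]) / 4
  res <- structure(list(
    D = D,
    D_se = unname(co["lag_s", "Std. Error"]) / 4,
    intercept = unname(co["(Intercept)", "Estimate"]),
    intercept_se = unname(co["(Intercept)", "Std. Error"]),
    n_lags_used = nrow(tab),
    residual = sum(stats::residuals(fit)^2),
    negative_D = D < 0
  ), class = "diffusion_fit")
  if (res$negative_D) warning("fitted diffusion coefficient is negative", call. = FALSE)
  res
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("diffusion fit over %d lags: D = %.4g +/- %.2g um^2/s, intercept = %.3g um^2%s\n",
              x$n_lags_used, x$D, x$D_se, x$intercept,
              if (x$negative_D) " [negative D flagged]" else ""))
  invisible(x)
}
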