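#' Melting temperature from a DSF melt curve
#'
#' Differential scanning fluorimetry analysis: the fluorescence trace is
#' normalised to its maximum, the first derivative is taken by central
#' differences on the temperature grid and lightly smoothed with a centred
#' running mean (`smooth_window` grid points; 5 points = 2 degC on the
#' default grid — fluorescence noise otherwise dominates the
#' point-to-point derivative), and the melting temperature is the
#' temperature of the derivative maximum, refined by parabolic
#' interpolation through the peak and its two neighbours (the 0.5 degC
#' acquisition grid would otherwise quantise Tm). The symmetric kernel
#' leaves the peak location of a noiseless transition unchanged. A curve
#' with no rising transition (derivative never positive) raises an
#' error. Local
#' derivative maxima beyond the global one are listed in the diagnostics,
#' since multi-domain proteins can show several transitions.
#'
#' @param melt A [curve_trace()] of kind `"melt"` with at least 10 points
#'   (temperature in degC).
#' @param smooth_window Odd number of grid points for the running-mean
#'   smoothing of the derivative (default 5; 1 disables smoothing).
#' @return Object of class `"tm_result"`: `tm` (degC),
#'   `derivative_peak_value` (1/degC, on the normalised curve), and
#'   `local_maxima` (data frame of all interior derivative peaks).
#' @export
fit_tm <- function(melt, smooth_window = 5) {
  stopifnot(inherits(melt, "curve_trace"))
  if (length(melt$x) < 10) stopf("a melt curve needs at least 10 points")
  if (smooth_window < 1 || smooth_window %% 2 != 1) {
    stopf("`smooth_window` must be an odd positive integer")
  }
  x <- melt$x
  y <- melt$y / max(melt$y)
  n <- length(x)
  # central differences at interior points
  dy <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  xm <- x[2:(n - 1)]
  if (smooth_window > 1 && length(dy) > smooth_window) {
    half <- (smooth_window - 1L) / 2L
    dy <- as.numeric(stats::filter(dy, rep(1 / smooth_window, smooth_window)))
    dy[seq_len(half)] <- dy[half + 1L]                  # pad the ends
    dy[(length(dy) - half + 1L):length(dy)] <- dy[length(dy) - half]
  }
  if (max(dy) <= 0) stopf("no melting transition: the curve never rises")
  i <- which.max(dy)
  tm <- xm[i]
  pk <- dy[i]
  if (i > 1 && i < length(dy)) {
    # parabola through (x[i-1..i+1], dy[i-1..i+1]); vertex refines Tm
    h1 <- xm[i] - xm[i - 1]; h2 <- xm[i + 1] - xm[i]
    d1 <- dy[i] - dy[i - 1]; d2 <- dy[i + 1] - dy[i]
    denom <- d1 * h2 + d2 * h1
    if (abs(denom) > 0) {
      shift <- 0.5 * (d1 * h2^2 - d2 * h1^2) / denom
      if (abs(shift) <= max(h1, h2)) tm <- xm[i] + shift
    }
  }
  local <- which(diff(sign(diff(dy))) == -2) + 1L
  local_df <- data.frame(temperature = xm[local], derivative = dy[local])
  # diagnostics list only substantial peaks (possible additional transitions)
  local_df <- local_df[local_df$derivative >= 0.25 * pk, , drop = FALSE]
  structure(list(tm = tm, derivative_peak_value = pk, local_maxima = local_df),
            class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("DSF melting temperature: Tm = %.2f degC (peak dF/dT = %.3g)\n",
              x$tm, x$derivative_peak_value))
  if (nrow(x$local_maxima) > 1) {
    cat(sprintf("  note: %d local derivative maxima (possible multiple transitions)\n",
                nrow(x$local_maxima)))
  }
  invisible(x)
}

#' Critical aggregation concentration from a DLS series
#'
#' Operationalises the "origin of slope" reading of a scattering-intensity
#' versus log-concentration series as a continuous two-segment linear fit:
#' for every interior grid position as candidate breakpoint, the model
#' `y = a + b*x + c*(x - bp)_+` is fit by least squares, the breakpoint
#' minimising the total squared residual wins, and
#' `CAC = 10^breakpoint`. The aggregation branch must be steeper than the
#' baseline (`c > 0`), and the two-segment model must beat a single line
#' by at least `f_threshold` on an F-ratio (2 extra parameters), otherwise
#' an error reports that no aggregation onset was detected.
#'
#' @param dls A [curve_trace()] of kind `"dls"`: `x` in log10(nM), at
#'   least 6 points.
#' @param f_threshold Minimum F-ratio of the two-segment over the
#'   single-line fit (default 10).
#' @return Object of class `"cac_result"`: `cac` (nM, = `10^breakpoint`),
#'   `breakpoint_log10`, `slope_below`, `slope_above`, `fit_error`
#'   (residual sum of squares) and `f_ratio`.
#' @export
fit_cac <- function(dls, f_threshold = 10) {
  stopifnot(inherits(dls, "curve_trace"))
  x <- dls$x; y <- dls$y
  n <- length(x)
  if (n < 6) stopf("a DLS series needs at least 6 points spanning the breakpoint")
  rss1 <- sum(stats::lm.fit(cbind(1, x), y)$residuals^2)
  if (rss1 <= .Machine$double.eps * max(1, mean(y)^2) * n) {
    stopf("no aggregation onset detected: a single line already fits the series")
  }
  # candidate breakpoints: interior grid positions with >= 2 points per side
  cand <- x[3:(n - 2)]
  best <- NULL
  for (bp in cand) {
    X <- cbind(1, x, pmax(x - bp, 0))
    f <- stats::lm.fit(X, y)
    rss <- sum(f$residuals^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(bp = bp, rss = rss, coef = f$coefficients)
    }
  }
  f_ratio <- if (best$rss <= .Machine$double.eps * max(1, rss1)) {
    Inf
  } else {
    ((rss1 - best$rss) / 2) / (best$rss / (n - 4))
  }
  if (!is.finite(best$coef[3]) || best$coef[3] <= 0 || f_ratio < f_threshold) {
    stopf("no aggregation onset detected (F-ratio %.3g, slope change %.3g)",
          f_ratio, best$coef[3])
  }
  structure(list(cac = 10^best$bp, breakpoint_log10 = best$bp,
                 slope_below = unname(best$coef[2]),
                 slope_above = unname(best$coef[2] + best$coef[3]),
                 fit_error = best$rss, f_ratio = f_ratio),
            class = "cac_result")
}

#' @export
print.cac_result <- function(x, ...) {
  cat(sprintf("DLS aggregation onset: CAC = %.3g nM (slopes %.3g -> %.3g per log10 unit)\n",
              x$cac, x$slope_below, x$slope_above))
  invisible(x)
}

#' Fluorescence lifetime by single-exponential tail fit
#'
#' FLIM-style lifetime estimation: nonlinear least squares of
#' `I(t) = I0 * exp(-t / tau) + offset` restricted to the decay tail
#' `t >= tail_start`, initialised from a log-linear fit of the
#' baseline-subtracted tail.
#'
#' @param decay A [curve_trace()] with time in ns and positive counts.
#' @param tail_start Start of the fitted tail in ns (default 0); at least
#'   10 points must remain.
#' @return Object of class `"lifetime_result"`: `tau_ns`, `I0`, `offset`,
#'   `rss`, `n_points`.
#' @export
fit_lifetime <- function(decay, tail_start = 0) {
  stopifnot(inherits(decay, "curve_trace"))
  keep <- decay$x >= tail_start
  t <- decay$x[keep]; y <- decay$y[keep]
  if (length(t) < 10) stopf("fewer than 10 points after tail_start = %g ns", tail_start)
  if (any(y <= 0)) stopf("decay counts must be positive")
  off0 <- min(y) * 0.5
  z <- pmax(y - off0, max(y) * 1e-9)
  ll <- stats::lm(log(z) ~ t)
  tau0 <- -1 / unname(stats::coef(ll)[2])
  if (!is.finite(tau0) || tau0 <= 0) {
    stopf("decay is not falling; cannot initialise a lifetime fit (slope %.3g)",
          unname(stats::coef(ll)[2]))
  }
  df <- data.frame(t = t, y = y)
  fit <- try(minpack.lm::nlsLM(
    y ~ I0 * exp(-t / tau) + C, data = df,
    start = list(I0 = max(y) - off0, tau = tau0, C = off0),
    lower = c(0, 1e-6, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
  if (inherits(fit, "try-error") || !fit$convInfo$isConv) {
    rss <- if (inherits(fit, "try-error")) NA_real_ else sum(stats::residuals(fit)^2)
    stopf("lifetime fit did not converge (RSS = %s)", format(rss))
  }
  co <- stats::coef(fit)
  structure(list(tau_ns = unname(co["tau"]), I0 = unname(co["I0"]),
                 offset = unname(co["C"]), rss = sum(stats::residuals(fit)^2),
                 n_points = length(t)),
            class = "lifetime_result")
}

#' @export
print.lifetime_result <- function(x, ...) {
  cat(sprintf("fluorescence lifetime tail fit: tau = %.3f ns (offset %.3g, %d points)\n",
              x$tau_ns, x$offset, x$n_points))
  invisible(x)
}
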